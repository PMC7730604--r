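#' Mutate an LTR sequence at fixed transition/transversion rates
#'
#' Applies the single-hit inverse of the Kimura two-parameter estimator: each
#' site independently receives a transition (A<->G, C<->T) with probability
#' `p_rate` or a transversion (uniform over the two transversion targets) with
#' probability `q_rate`. No indels are introduced, so the output has the same
#' length as the input. Used by the simulator to derive a 3' LTR from a 5' LTR
#' with a known expected divergence.
#'
#' @param seq Single nucleotide string over A, C, G, T.
#' @param p_rate Per-site transition probability, in `[0, 1]`.
#' @param q_rate Per-site transversion probability; `p_rate + q_rate <= 1`.
#' @param seed Optional integer seed; when supplied the mutation draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A nucleotide string of the same length as `seq`.
#' @examples
#' mutate_ltr("ACGTACGT", 0, 0)
#' mutate_ltr(strrep("A", 20), p_rate = 0.5, q_rate = 0, seed = 1)
#' @export
mutate_ltr <- function(seq, p_rate, q_rate, seed = NULL) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("`seq` must be a single non-empty nucleotide string")
  }
  assert_scalar_number(p_rate, "p_rate", 0, 1)
  assert_scalar_number(q_rate, "q_rate", 0, 1)
  if (p_rate + q_rate > 1) abort("`p_rate` + `q_rate` must not exceed 1")
  chars <- seq_to_chars(seq)
  if (!all(chars %in% DNA_BASES)) {
    abort("`seq` contains characters outside {A, C, G, T}")
  }
  draw <- function() {
    u <- runif(length(chars))
    v <- runif(length(chars)) # target choice for transversions
    out <- chars
    is_ts <- u < p_rate
    is_tv <- !is_ts & u < p_rate + q_rate
    out[is_ts] <- TRANSITION[chars[is_ts]]
    if (any(is_tv)) {
      tv_targets <- vapply(
        which(is_tv),
        function(i) TRANSVERSION[[chars[i]]][1 + (v[i] > 0.5)],
        character(1)
      )
      out[is_tv] <- tv_targets
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Peptide tags used to label simulated domain ORFs
#'
#' The simulator embeds one distinctive 12-residue tag per canonical
#' retroelement domain (GAG, AP, INT, RT, RH) into each planted ORF;
#' [label_orfs()] in tag mode recovers the label by exact substring match.
#' Tags contain no cysteine so they can never create a spurious CCHC
#' RNA-binding motif.
#'
#' @return Named character vector of peptide tags.
#' @export
domain_tags <- function() {
  c(
    GAG = "WGAGGKEWMDKW",
    AP  = "WAPDMKEWAPDW",
    INT = "WINTMKEWINTW",
    RT  = "WRTGMKEWRTGW",
    RH  = "WRHDMKEWRHDW"
  )
}

# The 14-residue CCHC zinc-knuckle (RNA-binding motif) planted into GAG ORFs.
RBM_PEPTIDE <- "CADCAKLMHTSQVC"

# Amino-acid alphabet used for ORF filler: no cysteine (so planted RBM counts
# are exact) and no tryptophan (tags are W-delimited).
FILLER_AA <- c(
  "A", "D", "E", "F", "G", "H", "I", "K", "L", "M",
  "N", "P", "Q", "R", "S", "T", "V", "Y"
)

#' Configuration for the synthetic retrotransposon dataset
#'
#' Defines the study conditions the simulator emulates: a small multi-
#' chromosome genome with planted LTR retrotransposons whose 3' LTR diverges
#' from the 5' LTR at controlled transition/transversion rates, internal ORFs
#' carrying recognizable domain tags and optional CCHC motifs, per-sample
#' expression evidence (read counts plus per-base depth) realizing target RPKM
#' and breadth, genes planted at controlled distances, and per-cultivar
#' genomic depth realizing planted copy-number multipliers.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_rte Number of planted retrotransposons.
#' @param n_expressed How many of them are truly expressed.
#' @param ltr_length Length of each LTR (bp).
#' @param orf_aa_length Length of each planted domain ORF (amino acids).
#' @param samples Tibble with columns `sample` and `condition`
#'   (`"non-stressed"` or `"stressed"`).
#' @param library_size Mapped-read count per RNA-seq sample.
#' @param expressed_rpkm,expressed_breadth Ranges (length-2) for expressed
#'   elements' target RPKM (log-uniform) and breadth of coverage.
#' @param decoy_rpkm,decoy_breadth Ranges for the failing evidence of decoy
#'   elements (low-RPKM and low-breadth decoy types respectively).
#' @param recent_fraction Fraction of elements planted with insertion times
#'   below `recent_mya`; recent times are drawn uniformly on
#'   `[0.05, 0.4]` Mya and late times on `[0.6, 2.5]` Mya.
#' @param recent_mya Recency boundary used when planting ages (Mya).
#' @param mutation_rate Substitutions per site per year used to convert
#'   planted times to divergence.
#' @param ts_tv_ratio Planted transition/transversion rate ratio.
#' @param copia_prob_expressed,copia_prob_other Probability that an
#'   expressed / non-expressed element belongs to the Ty1/Copia superfamily.
#' @param full_length_prob_expressed,full_length_prob_other Probability of
#'   planting all five domains (GAG, AP, INT, RT, RH).
#' @param gag_prob_expressed,gag_prob_other Probability that a non-full-length
#'   element carries a GAG ORF.
#' @param rbm_background_rate Probability that a planted non-GAG ORF carries
#'   one CCHC motif (the false-discovery background).
#' @param reverse_strand_orfs Plant ORFs on the reverse strand (exercises
#'   six-frame ORF finding).
#' @param gene_length Length of planted genes (bp).
#' @param proximity_probs Named probabilities for the four gene-proximity
#'   classes (`distant`, `close`, `overlapped`, `insertion`).
#' @param n_ref_genes Number of single-copy reference genes (for coverage
#'   normalization); planted far from every retrotransposon.
#' @param ref_gene_length Reference gene length (bp).
#' @param n_cultivars Number of cultivars with genomic depth data.
#' @param mobile_fraction Fraction of elements planted as mobile (extra
#'   copies, multiplier drawn on `multiplier_range`, in >= 2 cultivars).
#' @param multiplier_range Range of planted copy-number multipliers.
#' @param depth_base Baseline per-cultivar sequencing depth (reads).
#' @param depth_cv Coefficient of variation of multiplicative depth noise.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(
    n_chrom = 2L,
    chrom_length = 500000L,
    n_rte = 50L,
    n_expressed = 25L,
    ltr_length = 350L,
    orf_aa_length = 150L,
    samples = tibble(
      sample = c("leaf", "root", "NaCl_3h", "NaCl_12h", "PEG_6h"),
      condition = c(
        "non-stressed", "non-stressed",
        "stressed", "stressed", "stressed"
      )
    ),
    library_size = 2e7,
    expressed_rpkm = c(1, 50),
    expressed_breadth = c(0.8, 1.0),
    decoy_rpkm = c(0.01, 0.05),
    decoy_breadth = c(0.05, 0.2),
    recent_fraction = 0.5,
    recent_mya = 0.5,
    mutation_rate = 1.3e-8,
    ts_tv_ratio = 2,
    copia_prob_expressed = 0.7,
    copia_prob_other = 0.34,
    full_length_prob_expressed = 0.25,
    full_length_prob_other = 0.03,
    gag_prob_expressed = 0.8,
    gag_prob_other = 0.35,
    rbm_background_rate = 0.06,
    reverse_strand_orfs = FALSE,
    gene_length = 1200L,
    proximity_probs = c(
      distant = 0.6, close = 0.2, overlapped = 0.1, insertion = 0.1
    ),
    n_ref_genes = 5L,
    ref_gene_length = 1500L,
    n_cultivars = 13L,
    mobile_fraction = 0.57,
    multiplier_range = c(2, 4),
    depth_base = 30,
    depth_cv = 0.05) {
  cfg <- list(
    n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
    n_rte = as.integer(n_rte), n_expressed = as.integer(n_expressed),
    ltr_length = as.integer(ltr_length),
    orf_aa_length = as.integer(orf_aa_length),
    samples = as_tibble(samples), library_size = library_size,
    expressed_rpkm = expressed_rpkm, expressed_breadth = expressed_breadth,
    decoy_rpkm = decoy_rpkm, decoy_breadth = decoy_breadth,
    recent_fraction = recent_fraction, recent_mya = recent_mya,
    mutation_rate = mutation_rate, ts_tv_ratio = ts_tv_ratio,
    copia_prob_expressed = copia_prob_expressed,
    copia_prob_other = copia_prob_other,
    full_length_prob_expressed = full_length_prob_expressed,
    full_length_prob_other = full_length_prob_other,
    gag_prob_expressed = gag_prob_expressed,
    gag_prob_other = gag_prob_other,
    rbm_background_rate = rbm_background_rate,
    reverse_strand_orfs = isTRUE(reverse_strand_orfs),
    gene_length = as.integer(gene_length),
    proximity_probs = proximity_probs,
    n_ref_genes = as.integer(n_ref_genes),
    ref_gene_length = as.integer(ref_gene_length),
    n_cultivars = as.integer(n_cultivars),
    mobile_fraction = mobile_fraction,
    multiplier_range = multiplier_range,
    depth_base = depth_base, depth_cv = depth_cv
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_expressed > cfg$n_rte) {
    abort("`n_expressed` cannot exceed `n_rte`")
  }
  if (!all(c("sample", "condition") %in% names(cfg$samples))) {
    abort("`samples` needs columns `sample` and `condition`")
  }
  if (!all(cfg$samples$condition %in% c("non-stressed", "stressed"))) {
    abort("sample conditions must be 'non-stressed' or 'stressed'")
  }
  if (!setequal(
    names(cfg$proximity_probs),
    c("distant", "close", "overlapped", "insertion")
  )) {
    abort("`proximity_probs` must name distant, close, overlapped, insertion")
  }
  if (cfg$n_ref_genes < 1) abort("need at least one reference gene")
  if (cfg$n_cultivars < 2) abort("need at least two cultivars")
  if (cfg$depth_cv < 0) abort("`depth_cv` must be non-negative")
  invisible(cfg)
}

# Reverse-translate a peptide into a nucleotide string, choosing a random
# synonymous sense codon per residue (stop codons never emitted).
reverse_translate <- function(peptide) {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  by_aa <- split(names(sense), sense)
  aa <- seq_to_chars(peptide)
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

# Build one planted ORF: peptide starts with M, embeds the domain tag and
# `rbm_count` CCHC motifs, padded with cysteine-free filler. Returns the
# nucleotide cassette: in-frame TAA (terminates any upstream frame-mate),
# ATG + codons, trailing TAA.
build_orf_cassette <- function(domain, aa_length, rbm_count = 0L) {
  tag <- domain_tags()[[domain]]
  inserts <- c(tag, rep(RBM_PEPTIDE, rbm_count))
  filler_needed <- aa_length - 1L - sum(nchar(inserts))
  if (filler_needed < 2) {
    abort("`orf_aa_length` too short for the planted tag/motif content")
  }
  # distribute filler around the inserts (sizes >= 0, summing exactly)
  n_slots <- length(inserts) + 1L
  cuts <- sort(sample.int(filler_needed + 1L, n_slots - 1L,
    replace = TRUE
  ) - 1L)
  sizes <- diff(c(0L, cuts, filler_needed))
  filler <- vapply(
    sizes,
    function(k) paste(sample(FILLER_AA, k, replace = TRUE), collapse = ""),
    character(1)
  )
  pieces <- character(2L * length(inserts) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <- filler
  pieces[seq(2, length(pieces) - 1, by = 2)] <- inserts
  peptide <- paste0("M", paste(pieces, collapse = ""))
  stopifnot(nchar(peptide) == aa_length)
  list(
    peptide = peptide,
    nt = paste0("TAA", reverse_translate(peptide), "TAA")
  )
}

# Solve the planted (p_rate, q_rate) for a target K2P divergence k with a
# fixed transition/transversion ratio. Single-hit simulation is unbiased for
# (p, q) at these small rates, so E[k2p(p_hat, q_hat)] ~ k.
rates_for_k <- function(k, ts_tv_ratio) {
  if (k == 0) {
    return(c(p = 0, q = 0))
  }
  f <- function(p) k2p_distance(p, p / ts_tv_ratio) - k
  p <- stats::uniroot(f, c(1e-9, 0.2), tol = 1e-12)$root
  c(p = p, q = p / ts_tv_ratio)
}

#' Generate a synthetic genome with planted retrotransposon ground truth
#'
#' Writes a genome FASTA, an LTRdigest-style retrotransposon GFF3 (element +
#' two LTR features + protein-match features), a gene GFF3, per-sample depth
#' bedGraphs plus a read-count/library-size table realizing the planted RPKM
#' and breadth targets, and a per-cultivar depth table over every element and
#' the reference single-copy genes realizing the planted copy-number
#' multipliers. Identical `config` + `seed` produce byte-identical files.
#' Sequence, expression, and cultivar noise use separate random streams
#' derived from the master seed, so adding samples does not perturb the
#' genome sequence.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @return An `exrte_dataset` list: `config`, `seed`, `paths` (named file
#'   paths), and `truth` with tibbles `rtes`, `expression`, `genes`,
#'   `multipliers`.
#' @export
simulate_dataset <- function(config, seed, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  plan <- with_seed(
    derive_seed(seed, "placement"),
    plan_elements(config)
  )
  built <- with_seed(
    derive_seed(seed, "sequence"),
    build_genome(config, plan)
  )
  expr <- with_seed(
    derive_seed(seed, "expression"),
    plan_expression(config, built$rtes)
  )
  cult <- with_seed(
    derive_seed(seed, "cultivar"),
    plan_cultivars(config, built$rtes, built$genes)
  )

  paths <- write_dataset(config, built, expr, cult, out_dir)
  structure(
    list(
      config = config, seed = seed, paths = paths,
      truth = list(
        rtes = built$rtes, expression = expr$truth,
        genes = built$genes, multipliers = cult$multipliers
      )
    ),
    class = "exrte_dataset"
  )
}

# --- planning ---------------------------------------------------------------

# Decide, per element, everything that shapes its sequence and annotation.
plan_elements <- function(cfg) {
  n <- cfg$n_rte
  expressed <- c(
    rep(TRUE, cfg$n_expressed),
    rep(FALSE, n - cfg$n_expressed)
  )
  # decoy evidence types cycle so every failure mode is exercised
  decoy_type <- rep(NA_character_, n)
  decoy_type[!expressed] <- rep_len(
    c("low_rpkm", "low_breadth", "silent"),
    n - cfg$n_expressed
  )

  # planted ages -> divergence rates
  recent <- runif(n) < cfg$recent_fraction
  t_mya <- ifelse(recent, runif(n, 0.05, 0.4), runif(n, 0.6, 2.5))
  k_target <- 2 * cfg$mutation_rate * t_mya * 1e6
  rates <- t(vapply(k_target, rates_for_k, numeric(2),
    ts_tv_ratio = cfg$ts_tv_ratio
  ))

  # superfamily / clade labels
  copia_p <- ifelse(expressed, cfg$copia_prob_expressed, cfg$copia_prob_other)
  is_copia <- runif(n) < copia_p
  copia_clades <- c("Ale", "Ivana", "Tork")
  gypsy_clades <- c("Reina", "CRM", "Retand", "Tekay")
  clade <- ifelse(
    is_copia,
    sample(copia_clades, n, replace = TRUE),
    sample(gypsy_clades, n, replace = TRUE)
  )
  # the expressed set is planted without Tekay (high-copy clade analog)
  clade[expressed & clade == "Tekay"] <- "Reina"

  # domain plans
  full_p <- ifelse(
    expressed, cfg$full_length_prob_expressed, cfg$full_length_prob_other
  )
  gag_p <- ifelse(expressed, cfg$gag_prob_expressed, cfg$gag_prob_other)
  domains <- vector("list", n)
  for (i in seq_len(n)) {
    if (runif(1) < full_p[i]) {
      domains[[i]] <- RTE_DOMAINS
    } else {
      pool <- setdiff(RTE_DOMAINS, "GAG")
      picked <- sample(pool, sample.int(3, 1))
      if (runif(1) < gag_p[i]) picked <- c("GAG", picked)
      domains[[i]] <- RTE_DOMAINS[RTE_DOMAINS %in% picked]
    }
  }
  gag_rbm <- vapply(seq_len(n), function(i) {
    if (!"GAG" %in% domains[[i]]) {
      0L
    } else if (expressed[i]) {
      1L
    } else {
      sample(1:2, 1)
    }
  }, integer(1))

  prox <- sample(
    names(cfg$proximity_probs), n,
    replace = TRUE, prob = cfg$proximity_probs
  )
  mobile <- runif(n) < cfg$mobile_fraction

  tibble(
    rte_id = sprintf("TE%02d", seq_len(n)),
    expressed = expressed, decoy_type = decoy_type,
    true_t_years = t_mya * 1e6, true_k = k_target,
    p_rate = rates[, "p"], q_rate = rates[, "q"],
    recent = recent,
    superfamily = ifelse(is_copia, "Ty1/Copia", "Ty3/Gypsy"),
    clade = clade,
    domains = purrr::map(domains, identity),
    gag_rbm_count = gag_rbm,
    proximity_class = prox,
    mobile = mobile
  )
}

# Lay elements out in disjoint per-chromosome slots with random jitter:
# collision-free by construction, still randomly positioned, and each
# element keeps a private neighborhood for its planted gene. Reference
# genes go in a reserved tail of the last chromosome, far from every
# element.
build_genome <- function(cfg, plan) {
  n <- cfg$n_rte
  per_chrom <- ceiling(n / cfg$n_chrom)
  ref_tail <- cfg$n_ref_genes * (cfg$ref_gene_length + 2000L) + 10000L

  # sequence cassettes first (sequence stream)
  cassettes <- vector("list", n)
  for (i in seq_len(n)) {
    doms <- plan$domains[[i]]
    orf_parts <- purrr::map(doms, function(d) {
      rbm <- if (d == "GAG") {
        plan$gag_rbm_count[i]
      } else {
        as.integer(runif(1) < cfg$rbm_background_rate)
      }
      build_orf_cassette(d, cfg$orf_aa_length, rbm)
    })
    orf_nt <- purrr::map_chr(orf_parts, "nt")
    if (cfg$reverse_strand_orfs) orf_nt <- vapply(orf_nt, revcomp, character(1))
    spacers <- vapply(
      seq_len(length(orf_nt) + 1),
      function(j) random_dna(30L), character(1)
    )
    internal <- paste0(
      paste0(spacers[-length(spacers)], orf_nt, collapse = ""),
      spacers[length(spacers)]
    )
    ltr5 <- random_dna(cfg$ltr_length)
    ltr3 <- mutate_ltr(ltr5, plan$p_rate[i], plan$q_rate[i])
    # ORF offsets within the element (element coords, 0-based)
    off <- cfg$ltr_length
    orf_pos <- vector("list", length(orf_nt))
    cur <- off
    for (j in seq_along(orf_nt)) {
      cur <- cur + 30L # leading spacer
      orf_pos[[j]] <- c(start = cur + 3L, end = cur + nchar(orf_nt[j]) - 3L)
      cur <- cur + nchar(orf_nt[j])
    }
    cassettes[[i]] <- list(
      seq = paste0(ltr5, internal, ltr3),
      ltr_len = cfg$ltr_length,
      orf_domains = doms,
      orf_pos = orf_pos
    )
  }

  elem_len <- vapply(cassettes, function(x) nchar(x$seq), integer(1))
  # Each slot reserves a 4 kb left margin plus the element and its gene
  # neighborhood on the right; foreign genes therefore sit >= 4 kb away,
  # farther than any planted own-gene distance (<= 3.8 kb + gene length),
  # so the planted nearest-gene class is always the realized one.
  left_margin <- 4000L
  max_gene_reach <- 3800L + cfg$gene_length + 500L
  slot_need <- left_margin + elem_len + max_gene_reach
  slot_width <- (cfg$chrom_length - ref_tail) %/% per_chrom
  if (any(slot_need > slot_width)) {
    abort(paste0(
      "cannot place elements: a slot of ", slot_width,
      " bp cannot hold an element plus its gene neighborhood (need up to ",
      max(slot_need), " bp); increase `chrom_length` or reduce `n_rte`"
    ))
  }

  chrom_of <- rep(seq_len(cfg$n_chrom), each = per_chrom)[seq_len(n)]
  slot_of <- (seq_len(n) - 1L) %% per_chrom

  starts <- integer(n)
  gene_rows <- list()
  for (i in seq_len(n)) {
    jitter <- sample.int(slot_width - slot_need[i] + 1L, 1) - 1L
    starts[i] <- slot_of[i] * slot_width + left_margin + jitter
  }

  rtes <- plan |>
    mutate(
      chrom = sprintf("chr%d", chrom_of),
      start = starts,
      end = starts + elem_len,
      strand = "+",
      ltr5_start = starts,
      ltr5_end = starts + cfg$ltr_length,
      ltr3_start = starts + elem_len - cfg$ltr_length,
      ltr3_end = starts + elem_len,
      length = elem_len
    )

  # planted genes at controlled distances (annotation only; genes carry no
  # dedicated sequence, which is adequate because no homology search is in
  # scope)
  gl <- cfg$gene_length
  for (i in seq_len(n)) {
    cls <- rtes$proximity_class[i]
    s <- rtes$start[i]
    e <- rtes$end[i]
    gene <- switch(cls,
      insertion = c(s - 300L, e + 300L),
      overlapped = c(e - 200L, e - 200L + gl),
      close = {
        gap <- sample(100:900, 1)
        c(e + gap, e + gap + gl)
      },
      distant = {
        gap <- sample(1500:3800, 1)
        c(e + gap, e + gap + gl)
      }
    )
    gene_rows[[i]] <- tibble(
      gene_id = sprintf("gene_%s", rtes$rte_id[i]),
      chrom = rtes$chrom[i], start = gene[1], end = gene[2],
      class = cls, rte_id = rtes$rte_id[i], is_reference = FALSE
    )
  }
  true_dist <- vapply(seq_len(n), function(i) {
    g <- gene_rows[[i]]
    max(0, as.numeric(g$start) - as.numeric(rtes$end[i]))
  }, numeric(1))
  rtes$gene_distance <- ifelse(
    rtes$proximity_class %in% c("insertion", "overlapped"), 0L, true_dist
  )

  # reference single-copy genes in the reserved tail of the last chromosome
  tail_start <- per_chrom * slot_width + 10000L
  ref <- tibble(
    gene_id = sprintf("refgene_%02d", seq_len(cfg$n_ref_genes)),
    chrom = sprintf("chr%d", cfg$n_chrom),
    start = tail_start +
      (seq_len(cfg$n_ref_genes) - 1L) * (cfg$ref_gene_length + 2000L),
    end = tail_start +
      (seq_len(cfg$n_ref_genes) - 1L) * (cfg$ref_gene_length + 2000L) +
      cfg$ref_gene_length,
    class = NA_character_, rte_id = NA_character_, is_reference = TRUE
  )
  genes <- bind_rows(bind_rows(gene_rows), ref)

  # assemble chromosome sequences: random background, cassettes pasted in
  chroms <- character(cfg$n_chrom)
  for (cc in seq_len(cfg$n_chrom)) {
    seq <- random_dna(cfg$chrom_length)
    idx <- which(chrom_of == cc)
    for (i in idx) {
      substr(seq, starts[i] + 1L, starts[i] + elem_len[i]) <- cassettes[[i]]$seq
    }
    chroms[cc] <- seq
  }
  names(chroms) <- sprintf("chr%d", seq_len(cfg$n_chrom))

  rtes$orf_domains <- purrr::map(cassettes, "orf_domains")
  rtes$orf_pos <- purrr::map(cassettes, "orf_pos")
  list(rtes = rtes, genes = genes, chroms = chroms)
}

# Expression targets and realized counts/depth per sample.
plan_expression <- function(cfg, rtes) {
  samples <- cfg$samples
  n_s <- nrow(samples)
  rows <- list()
  for (i in seq_len(nrow(rtes))) {
    len <- rtes$length[i]
    if (rtes$expressed[i]) {
      # expressed in a random non-empty subset of samples (always >= 1 from
      # each condition pool is not enforced; the per-sample pattern is free)
      on <- runif(n_s) < 0.7
      if (!any(on)) on[sample.int(n_s, 1)] <- TRUE
      rpkm <- ifelse(
        on,
        exp(runif(n_s, log(cfg$expressed_rpkm[1]), log(cfg$expressed_rpkm[2]))),
        0
      )
      breadth <- ifelse(
        on, runif(n_s, cfg$expressed_breadth[1], cfg$expressed_breadth[2]), 0
      )
    } else {
      dt <- rtes$decoy_type[i]
      if (dt == "low_rpkm") {
        rpkm <- runif(n_s, cfg$decoy_rpkm[1], cfg$decoy_rpkm[2])
        breadth <- runif(n_s, cfg$expressed_breadth[1], cfg$expressed_breadth[2])
      } else if (dt == "low_breadth") {
        rpkm <- exp(runif(n_s, log(1), log(10)))
        breadth <- runif(n_s, cfg$decoy_breadth[1], cfg$decoy_breadth[2])
      } else {
        rpkm <- rep(0, n_s)
        breadth <- rep(0, n_s)
      }
    }
    count <- round(rpkm * len * cfg$library_size / 1e9)
    rows[[i]] <- tibble(
      rte_id = rtes$rte_id[i], sample = samples$sample,
      condition = samples$condition,
      target_rpkm = rpkm, target_breadth = breadth,
      read_count = as.integer(count),
      library_size = cfg$library_size
    )
  }
  truth <- bind_rows(rows)
  list(truth = truth)
}

# Per-cultivar depth over elements and reference genes, realizing planted
# copy-number multipliers; depth scales linearly with copy number with
# multiplicative gaussian noise of coefficient of variation `depth_cv`.
plan_cultivars <- function(cfg, rtes, genes) {
  cultivars <- sprintf("cv%02d", seq_len(cfg$n_cultivars))
  scale <- runif(cfg$n_cultivars, 0.7, 1.3) # library-size differences

  mult_rows <- list()
  for (i in seq_len(nrow(rtes))) {
    m <- rep(1, cfg$n_cultivars)
    n_extra <- if (rtes$mobile[i]) {
      sample(2:4, 1)
    } else {
      sample(0:1, 1)
    }
    if (n_extra > 0) {
      idx <- sample.int(cfg$n_cultivars, n_extra)
      m[idx] <- runif(n_extra, cfg$multiplier_range[1], cfg$multiplier_range[2])
    }
    mult_rows[[i]] <- tibble(
      rte_id = rtes$rte_id[i], cultivar = cultivars,
      multiplier = m, n_extra = n_extra
    )
  }
  multipliers <- bind_rows(mult_rows)

  noise <- function(k) {
    if (cfg$depth_cv == 0) rep(1, k) else pmax(0.01, rnorm(k, 1, cfg$depth_cv))
  }
  depth_rte <- multipliers |>
    mutate(
      feature_type = "rte",
      mean_depth = cfg$depth_base * scale[match(.data$cultivar, cultivars)] *
        .data$multiplier * noise(dplyr::n())
    ) |>
    select(
      feature_id = "rte_id", "feature_type", "cultivar", "mean_depth"
    )
  ref <- genes |> filter(.data$is_reference)
  depth_ref <- tidyr::expand_grid(
    feature_id = ref$gene_id, cultivar = cultivars
  ) |>
    mutate(
      feature_type = "reference_gene",
      mean_depth = cfg$depth_base * scale[match(.data$cultivar, cultivars)] *
        noise(dplyr::n())
    ) |>
    select("feature_id", "feature_type", "cultivar", "mean_depth")
  list(
    multipliers = multipliers,
    depth = bind_rows(depth_rte, depth_ref)
  )
}

# --- serialization ----------------------------------------------------------

# Minimal deterministic GFF3 emitter for the dialect this package consumes
# (parsing is done by rtracklayer; emission avoids volatile header lines so
# identical runs are byte-identical).
write_gff3_lines <- function(df, path) {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\texrte_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
      df$chrom, df$type, df$start + 1L, df$end, df$strand, df$attributes
    )
  )
  readr::write_lines(lines, path)
}

write_dataset <- function(cfg, built, expr, cult, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  paths <- list(
    genome = p("genome.fa"),
    rte_gff = p("rtes.gff3"),
    gene_gff = p("genes.gff3"),
    counts = p("counts.tsv"),
    libraries = p("library_sizes.tsv"),
    cultivar_depth = p("cultivar_depth.tsv"),
    truth = p("truth.json")
  )

  genome <- Biostrings::DNAStringSet(built$chroms)
  Biostrings::writeXStringSet(genome, paths$genome)

  # retrotransposon GFF3: element + two LTRs + protein_match children
  rtes <- built$rtes
  feat <- list()
  for (i in seq_len(nrow(rtes))) {
    id <- rtes$rte_id[i]
    feat[[length(feat) + 1]] <- tibble(
      chrom = rtes$chrom[i], type = "LTR_retrotransposon",
      start = rtes$start[i], end = rtes$end[i], strand = rtes$strand[i],
      attributes = sprintf(
        "ID=%s;superfamily=%s;clade=%s",
        id, rtes$superfamily[i], rtes$clade[i]
      )
    )
    feat[[length(feat) + 1]] <- tibble(
      chrom = rtes$chrom[i], type = "long_terminal_repeat",
      start = c(rtes$ltr5_start[i], rtes$ltr3_start[i]),
      end = c(rtes$ltr5_end[i], rtes$ltr3_end[i]),
      strand = rtes$strand[i],
      attributes = sprintf("Parent=%s", id)
    )
    doms <- rtes$orf_domains[[i]]
    pos <- rtes$orf_pos[[i]]
    for (j in seq_along(doms)) {
      feat[[length(feat) + 1]] <- tibble(
        chrom = rtes$chrom[i], type = "protein_match",
        start = rtes$start[i] + pos[[j]]["start"],
        end = rtes$start[i] + pos[[j]]["end"],
        strand = rtes$strand[i],
        attributes = sprintf(
          "Parent=%s;Name=%s;aa_length=%d", id, doms[j], cfg$orf_aa_length
        )
      )
    }
  }
  type_order <- c("LTR_retrotransposon", "long_terminal_repeat", "protein_match")
  gff <- bind_rows(feat) |>
    mutate(.rank = match(.data$type, type_order)) |>
    arrange(.data$chrom, .data$start, .data$.rank) |>
    select(-".rank")
  write_gff3_lines(gff, paths$rte_gff)

  genes <- built$genes |>
    mutate(
      type = "gene",
      attributes = sprintf("ID=%s", .data$gene_id),
      strand = "+"
    ) |>
    arrange(.data$chrom, .data$start)
  write_gff3_lines(genes, paths$gene_gff)

  truth <- expr$truth
  readr::write_tsv(
    truth |> select("rte_id", "sample", "read_count"),
    paths$counts
  )
  readr::write_tsv(
    cfg$samples |> mutate(library_size = cfg$library_size),
    paths$libraries
  )

  # per-sample depth bedGraph realizing the target breadth exactly:
  # constant depth over the leading `round(breadth * length)` bases
  depth_paths <- character(0)
  for (s in cfg$samples$sample) {
    rows <- truth |>
      filter(.data$sample == s, .data$read_count > 0) |>
      left_join(
        rtes |> select("rte_id", "chrom", "start", "length"),
        by = "rte_id"
      ) |>
      mutate(
        covered = pmax(
          0L,
          as.integer(round(.data$target_breadth * .data$length))
        ),
        depth = pmax(1L, as.integer(
          round(.data$read_count * 100 / pmax(.data$covered, 1))
        ))
      ) |>
      filter(.data$covered > 0)
    f <- p(sprintf("depth_%s.bedGraph", s))
    lines <- sprintf(
      "%s\t%d\t%d\t%d",
      rows$chrom, rows$start, rows$start + rows$covered, rows$depth
    )
    ord <- order(rows$chrom, rows$start)
    readr::write_lines(lines[ord], f)
    depth_paths[s] <- f
  }
  paths$depth <- depth_paths

  readr::write_tsv(cult$depth, paths$cultivar_depth)

  truth_dump <- list(
    rtes = built$rtes |>
      select(-"orf_pos") |>
      mutate(domains = purrr::map_chr(
        .data$domains, paste,
        collapse = ";"
      )) |>
      mutate(orf_domains = purrr::map_chr(
        .data$orf_domains, paste,
        collapse = ";"
      )),
    expression = expr$truth,
    genes = built$genes,
    multipliers = cult$multipliers
  )
  jsonlite::write_json(
    truth_dump, paths$truth,
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  paths
}
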