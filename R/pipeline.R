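# End-to-end orchestration: catalog -> expression -> age -> ORF/motif ->
# proximity -> mobilome -> enrichment, with deterministic tabular outputs
# and a machine-readable funnel summary.

#' Pipeline configuration
#'
#' Houses every threshold of the survey, at its standard default: candidate
#' length > 500 bp with at least one canonical domain hit; expression called
#' at RPKM >= 0.25 and breadth >= 0.60 with best domain match >= 50 aa;
#' redundancy removed above 95% global identity; ORFs >= 300 nt; insertion
#' dating at r = 1.3e-8 substitutions/site/year with the recent/late
#' boundary at 0.5 Mya; gene proximity split at 1 kb; ACM cutoff derived
#' from single-copy reference genes (or fixed, e.g. 1.7) with group 1
#' requiring additional copies in more than one cultivar.
#'
#' @param min_rte_length Candidate length cutoff (bp, exclusive).
#' @param required_domains Domains accepted as candidate evidence.
#' @param rpkm_min,cov_min,min_domain_aa Expression-call thresholds.
#' @param dedup_identity Redundancy identity cutoff.
#' @param min_orf_nt Minimum ORF length (nt).
#' @param mutation_rate Substitutions per site per year.
#' @param recent_boundary_years Recent/late boundary (years).
#' @param close_gene_bp Close/distant gene-proximity boundary (bp).
#' @param acm_cutoff `"derived"` or a fixed numeric cutoff.
#' @param strict_same_sample,pooled_coverage Expression-call modes; see
#'   [call_expressed()].
#' @param seed Master seed recorded with the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(min_rte_length = 500,
                            required_domains = RTE_DOMAINS,
                            rpkm_min = 0.25,
                            cov_min = 0.60,
                            min_domain_aa = 50,
                            dedup_identity = 0.95,
                            min_orf_nt = 300,
                            mutation_rate = 1.3e-8,
                            recent_boundary_years = 5e5,
                            close_gene_bp = 1000,
                            acm_cutoff = "derived",
                            strict_same_sample = FALSE,
                            pooled_coverage = FALSE,
                            seed = 1L) {
  cfg <- list(
    min_rte_length = min_rte_length, required_domains = required_domains,
    rpkm_min = rpkm_min, cov_min = cov_min, min_domain_aa = min_domain_aa,
    dedup_identity = dedup_identity, min_orf_nt = min_orf_nt,
    mutation_rate = mutation_rate,
    recent_boundary_years = recent_boundary_years,
    close_gene_bp = close_gene_bp, acm_cutoff = acm_cutoff,
    strict_same_sample = isTRUE(strict_same_sample),
    pooled_coverage = isTRUE(pooled_coverage),
    seed = as.integer(seed)
  )
  assert_scalar_number(cfg$min_rte_length, "min_rte_length", 0)
  assert_scalar_number(cfg$rpkm_min, "rpkm_min", 0)
  assert_scalar_number(cfg$cov_min, "cov_min", 0, 1)
  assert_scalar_number(cfg$min_domain_aa, "min_domain_aa", 0)
  assert_scalar_number(cfg$dedup_identity, "dedup_identity", 0, 1)
  assert_scalar_number(cfg$min_orf_nt, "min_orf_nt", 3)
  assert_scalar_number(cfg$mutation_rate, "mutation_rate", 1e-12, 1)
  assert_scalar_number(cfg$recent_boundary_years, "recent_boundary_years", 0)
  assert_scalar_number(cfg$close_gene_bp, "close_gene_bp", 0)
  if (!identical(cfg$acm_cutoff, "derived")) {
    assert_scalar_number(cfg$acm_cutoff, "acm_cutoff", 1)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full expressed-retrotransposon survey
#'
#' Executes every stage on one set of inputs and writes one TSV per stage, a
#' JSON summary with the counts at every filter step, and a plain-text log
#' (package version, config hash, seed). Given identical inputs and
#' configuration the outputs are byte-identical. An empty annotation
#' produces empty but valid outputs with a warning.
#'
#' @param inputs Either an `exrte_dataset` from [simulate_dataset()] or a
#'   named list of paths: `genome`, `rte_gff`, `gene_gff`, `counts`,
#'   `libraries`, `depth` (named vector of bedGraphs keyed by sample),
#'   `cultivar_depth`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage tibbles and the `summary` list.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(inputs, "exrte_dataset")) inputs <- inputs$paths
  need <- c(
    "genome", "rte_gff", "gene_gff", "counts", "libraries",
    "depth", "cultivar_depth"
  )
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    abort(sprintf("missing input(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
    message(sprintf(
      "[%s] done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    res
  }

  catalog <- stage("catalog", read_ltr_gff(inputs$rte_gff))
  if (nrow(catalog) == 0) {
    warn("empty retrotransposon annotation; writing empty outputs")
  }
  candidates <- stage("candidates", filter_candidates(
    catalog, config$min_rte_length, config$required_domains
  ))

  genome <- Biostrings::readDNAStringSet(inputs$genome)
  seqs <- rte_sequences(candidates, genome, "element")

  profiles <- stage("expression", expression_profiles(
    candidates, inputs$counts, inputs$libraries, inputs$depth
  ))
  calls <- stage("calls", call_expressed(
    profiles, candidates,
    rpkm_min = config$rpkm_min, cov_min = config$cov_min,
    min_domain_aa = config$min_domain_aa,
    seqs = seqs, dedup_identity = config$dedup_identity,
    strict_same_sample = config$strict_same_sample,
    pooled_coverage = config$pooled_coverage
  ))
  partition <- if (nrow(profiles)) {
    condition_partition(profiles, config$rpkm_min, config$cov_min)
  } else {
    tibble(non_stressed_only = 0L, stressed_only = 0L, both = 0L)
  }

  ages <- stage("ages", if (nrow(calls)) {
    estimate_ages(
      calls, genome, config$mutation_rate, config$recent_boundary_years
    )
  } else {
    tibble(rte_id = character(), k = numeric(), t_years = numeric(),
      t_mya = numeric(), recency = character(), datable = logical(),
      p = numeric(), q = numeric(), n_columns = integer()
    )
  })

  orfs <- stage("orfs", {
    o <- find_orfs_catalog(calls, genome, config$min_orf_nt)
    o <- label_orfs(o)
    if (nrow(o)) {
      o |> left_join(calls |> select("rte_id", "set"), by = "rte_id")
    } else {
      o
    }
  })
  rbm <- compute_rbm_fdr(orfs)
  domains <- summarize_domains(orfs, calls)

  genes <- stage("genes", read_gene_gff(inputs$gene_gff))
  proximity <- stage("proximity", classify_gene_proximity(
    calls, genes, config$close_gene_bp
  ))

  acm <- stage("mobilome", acm_profiles(
    inputs$cultivar_depth, config$acm_cutoff
  ))

  enrichment <- stage("enrichment", {
    per_rte <- calls |>
      select("rte_id", "set", "superfamily", "clade") |>
      left_join(ages |> select("rte_id", "recency"), by = "rte_id") |>
      left_join(domains$per_rte |> select(-dplyr::any_of("set")),
        by = "rte_id"
      ) |>
      left_join(proximity |> select("rte_id", "distance"), by = "rte_id") |>
      mutate(
        has_gag = stringr::str_detect(.data$domains, "GAG"),
        recent = .data$recency == "recent"
      )
    if (nrow(per_rte) && dplyr::n_distinct(per_rte$set) == 2) {
      enrichment_report(
        per_rte,
        categorical = c(
          "superfamily", "clade", "recent", "has_gag", "full_length"
        ),
        continuous = c("max_orf_nt", "distance")
      )
    } else {
      NULL
    }
  })

  funnel <- list(
    n_annotated = nrow(catalog),
    n_candidates = nrow(candidates),
    n_rpkm_pass = sum(calls$passes_rpkm),
    n_rpkm_and_coverage = sum(calls$passes_rpkm & calls$passes_coverage),
    n_curated = sum(
      calls$passes_rpkm & calls$passes_coverage & calls$passes_domain
    ),
    n_exrte = sum(calls$is_expressed),
    n_nexrte = sum(!calls$is_expressed)
  )
  summary <- list(
    funnel = funnel,
    condition_partition = as.list(partition),
    n_recent_exrte = sum(
      ages$recency[ages$rte_id %in% calls$rte_id[calls$is_expressed]] ==
        "recent",
      na.rm = TRUE
    ),
    rbm = as.list(rbm$summary),
    acm_cutoff = acm$cutoff,
    acm_groups = as.list(table(acm$groups$group)),
    seed = config$seed
  )

  # deterministic outputs: stage tables, summary JSON, plain log
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name))
  }
  w(write_flat_calls(calls), "catalog.tsv")
  w(profiles, "expression.tsv")
  w(ages, "ages.tsv")
  w(orfs |> select(-dplyr::any_of("protein")), "orfs.tsv")
  w(domains$per_rte, "domain_summary.tsv")
  w(domains$combinations, "domain_combinations.tsv")
  w(proximity, "proximity.tsv")
  w(tidy(acm), "acm.tsv")
  if (!is.null(enrichment)) w(tidy(enrichment), "enrichment.tsv")
  jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cfg_for_log <- config
  readr::write_lines(
    c(
      sprintf("exrte version: %s", as.character(utils::packageVersion("exrte"))),
      sprintf("config hash: %s", rlang::hash(cfg_for_log)),
      sprintf("seed: %d", config$seed)
    ),
    file.path(out_dir, "run_log.txt")
  )

  invisible(list(
    catalog = catalog, candidates = candidates, profiles = profiles,
    calls = calls, partition = partition, ages = ages, orfs = orfs,
    rbm = rbm, domains = domains, proximity = proximity, acm = acm,
    enrichment = enrichment, summary = summary
  ))
}

# flat, TSV-friendly view of the expression calls
write_flat_calls <- function(calls) {
  calls |>
    mutate(domains = purrr::map_chr(
      .data$domain_hits,
      function(h) paste(sort(unique(h$domain)), collapse = ";")
    )) |>
    select(-"domain_hits")
}
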