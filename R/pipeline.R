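#' Build a pipeline configuration
#'
#' Assembles and validates the configuration for the end-to-end synthetic
#' study: cohort generation, Moran simulation, trend statistics,
#' tract diversity, ROH analyses, admixture mapping and polygenic-score
#' evaluation. Unknown keys are rejected.
#'
#' @param preset `"tiny"` (seconds-scale smoke test) or `"default"`
#'   (desk-scale analysis).
#' @param seed Run-level seed; every stage derives its own stream via
#'   [child_seed()].
#' @param out_dir Output directory for stage artifacts.
#' @param overrides Named list of per-stage overrides, e.g.
#'   `list(cohort = list(n = 500))`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("tiny", "default"), seed = 1,
                            out_dir = tempfile("admixdyn_run_"),
                            overrides = list()) {
  preset <- match.arg(preset)
  base <- if (preset == "tiny") {
    list(
      cohort = list(n = 80),
      map = list(n_chrom = 2, chrom_bp = 2e7),
      tracts = list(lambda_gens = 10, subset_n = NULL),
      genotypes = list(n_sites = 200, fst_target = 0.1),
      roh = list(),
      gwas = list(n_causal = 10, effect_sd = 0.5),
      moran = list(N0 = 100, generations = 1, AM = 0.75, FAI = 0.8),
      loess = list(n_iter = 50),
      pi = list(n_boot = 20),
      prs = list(p_threshold = 5e-8, window_bp = 1e6)
    )
  } else {
    list(
      cohort = list(n = 3622),
      map = list(n_chrom = 4, chrom_bp = 5e7),
      # sequence-level stages run on a seeded subcohort; cohort-level
      # regressions always use the full table
      tracts = list(lambda_gens = 10, subset_n = 500),
      genotypes = list(n_sites = 2000, fst_target = 0.1),
      roh = list(),
      gwas = list(n_causal = 50, effect_sd = 0.5),
      moran = list(N0 = 1000, generations = 2, AM = 0.75, FAI = 0.8),
      loess = list(n_iter = 1000),
      pi = list(n_boot = 200),
      prs = list(p_threshold = 5e-8, window_bp = 1e6)
    )
  }
  bad <- setdiff(names(overrides), names(base))
  if (length(bad)) config_error(paste("unknown config blocks:",
                                      paste(bad, collapse = ", ")))
  for (blk in names(overrides)) {
    ov <- overrides[[blk]]
    if (blk %in% c("cohort", "roh")) {
      # these blocks pass through dedicated constructors that validate keys
      base[[blk]] <- utils::modifyList(base[[blk]], ov)
    } else {
      bad <- setdiff(names(ov), names(base[[blk]]))
      if (length(bad)) config_error(paste0("unknown keys in '", blk, "': ",
                                           paste(bad, collapse = ", ")))
      base[[blk]] <- utils::modifyList(base[[blk]], ov)
    }
  }
  cfg <- c(base, list(preset = preset, seed = seed, out_dir = out_dir))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path A YAML (`.yaml`/`.yml`) or JSON file with top-level keys
#'   `preset`, `seed`, `out_dir` and per-stage override blocks. Note that
#'   YAML 1.1 reads bare `n`/`y`/`yes`/`no` as booleans, so the cohort
#'   size key must be written quoted (`"n": 3622`).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("preset", "seed", "out_dir")
  blocks <- raw[setdiff(names(raw), known_top)]
  pipeline_config(preset = raw$preset %||% "tiny",
                  seed = raw$seed %||% 1,
                  out_dir = raw$out_dir %||% tempfile("admixdyn_run_"),
                  overrides = blocks)
}

#' Run the end-to-end synthetic study
#'
#' Executes generation and analysis stages in dependency order, writes
#' every artifact as plain text under `config$out_dir`, and records a
#' manifest with MD5 checksums; identical config and seed give identical
#' checksums. A stage failure aborts with the stage name after persisting
#' the partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly a list: `manifest` (data.frame of stage, file, md5),
#'   `summary` (headline statistics of each analysis stage), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  summary <- list()
  seed <- config$seed

  persist <- function() {
    mpath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
    mpath
  }
  add_artifact <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      persist()
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  map <- genome_map(rep(config$map$chrom_bp, config$map$n_chrom))

  cohort <- run_stage("cohort", function() {
    cc <- do.call(cohort_config, config$cohort)
    coh <- generate_cohort(cc, seed = child_seed(seed, "cohort"))
    write_cohort_tsv(coh, file.path(config$out_dir, "cohort.tsv"))
    add_artifact("cohort", file.path(config$out_dir, "cohort.tsv"))
    coh
  })

  sub_cohort <- run_stage("subset", function() {
    k <- config$tracts$subset_n
    if (is.null(k) || k >= nrow(cohort)) return(cohort)
    set.seed(child_seed(seed, "subset"))
    out <- cohort[sort(sample.int(nrow(cohort), k)), , drop = FALSE]
    attr(out, "config") <- attr(cohort, "config")
    out
  })

  tracts <- run_stage("tracts", function() {
    tr <- generate_local_ancestry(sub_cohort, map,
                                  lambda_gens = config$tracts$lambda_gens,
                                  seed = child_seed(seed, "tracts"))
    write_tracts_tsv(tr, file.path(config$out_dir, "tracts.tsv"))
    add_artifact("tracts", file.path(config$out_dir, "tracts.tsv"))
    tr
  })

  geno <- run_stage("genotypes", function() {
    fr <- ancestry_panel_freqs(map, n_sites = config$genotypes$n_sites,
                               fst_target = config$genotypes$fst_target,
                               seed = child_seed(seed, "freqs"))
    g <- generate_genotypes(tracts, fr, seed = child_seed(seed, "genotypes"))
    write_vcf(g, file.path(config$out_dir, "genotypes.vcf"))
    add_artifact("genotypes", file.path(config$out_dir, "genotypes.vcf"))
    g
  })

  roh <- run_stage("roh", function() {
    rc <- do.call(roh_config, config$roh)
    rr <- generate_roh(sub_cohort, map, rc, seed = child_seed(seed, "roh"))
    rr <- classify_roh(rr, fixed_class_boundaries())
    write_tracts_tsv(rr, file.path(config$out_dir, "roh.tsv"))
    add_artifact("roh", file.path(config$out_dir, "roh.tsv"))
    rr
  })

  gw <- run_stage("gwas", function() {
    gg <- generate_gwas_summary(geno$sites,
                                n_causal = config$gwas$n_causal,
                                effect_sd = config$gwas$effect_sd,
                                seed = child_seed(seed, "gwas"))
    write_gwas_tsv(gg$summary, file.path(config$out_dir, "gwas_summary.tsv"))
    add_artifact("gwas", file.path(config$out_dir, "gwas_summary.tsv"))
    gg
  })
  sub_cohort <- run_stage("height", function() {
    attach_height(sub_cohort, geno, gw$effects,
                  seed = child_seed(seed, "height"))
  })

  run_stage("moran", function() {
    mp <- do.call(moran_params, config$moran)
    tr <- moran_run(mp, seed = child_seed(seed, "moran"))
    write_trajectory_json(tr, file.path(config$out_dir, "trajectory.json"))
    add_artifact("moran", file.path(config$out_dir, "trajectory.json"))
    summary$moran <<- list(pct_change = tr$pct_change, parent_r = tr$parent_r,
                           final_mean = tr$final_mean)
    NULL
  })

  run_stage("trends", function() {
    ft <- fit_trend(cohort)
    env <- bootstrap_loess(cohort, n_iter = config$loess$n_iter,
                           seed = child_seed(seed, "loess"))
    pc <- parental_correlation(cohort$parent1_ai, cohort$parent2_ai)
    summary$trends <<- list(
      birth_year_effect = unname(birth_year_effect(ft)[["estimate"]]),
      envelope_width = mean(env$upper - env$lower),
      parental_r = pc$r)
    NULL
  })

  run_stage("tract_stats", function() {
    dec <- stats::setNames(decade_of(sub_cohort$birth_year),
                           sub_cohort$individual_id)
    pi_tab <- pi_within_ancestry(tracts, geno, dec,
                                 n_boot = config$pi$n_boot,
                                 seed = child_seed(seed, "pi"))
    utils::write.table(pi_tab, file.path(config$out_dir, "pi_by_decade.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact("tract_stats", file.path(config$out_dir, "pi_by_decade.tsv"))
    fst_tab <- fst_between_groups(tracts, geno, dec)
    tlr <- tract_length_regression(tracts, dec)
    conc <- tract_global_concordance(tracts, sub_cohort, map = map)
    summary$tract_stats <<- list(
      mean_pi = mean(pi_tab$pi, na.rm = TRUE),
      mean_fst = mean(fst_tab$fst, na.rm = TRUE),
      decade_main_effect = tlr$coefficients["A_dec", "estimate"],
      concordance_r = stats::cor(conc$tract_fraction, conc$anc_ai))
    NULL
  })

  run_stage("roh_stats", function() {
    ov <- overlap_by_ancestry(roh, tracts, cohort = sub_cohort)
    utils::write.table(ov, file.path(config$out_dir, "roh_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact("roh_stats", file.path(config$out_dir, "roh_overlap.tsv"))
    tr_tab <- roh_trend(ov, sub_cohort)
    tot <- tr_tab[tr_tab$size_class == "total" & !tr_tab$normalized, ]
    summary$roh_stats <<- list(
      tau_ai = tot$tau[tot$label == "AI"],
      tau_eur = tot$tau[tot$label == "EUR"])
    NULL
  })

  run_stage("admixmap", function() {
    dos <- ancestry_dosage(tracts, geno$sites)
    sc <- scan_linear(dos, sub_cohort)
    th <- effective_tests_threshold(dos, geno$sites)
    utils::write.table(sc, file.path(config$out_dir, "admixmap_linear.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact("admixmap", file.path(config$out_dir, "admixmap_linear.tsv"))
    summary$admixmap <<- list(threshold = th$threshold,
                              total_blocks = th$total_blocks,
                              n_hits = sum(sc$p < th$threshold, na.rm = TRUE))
    NULL
  })

  run_stage("prs", function() {
    sel <- select_prs_snps(gw$summary, p_threshold = config$prs$p_threshold,
                           window_bp = config$prs$window_bp)
    phs <- compute_phs(geno, sel)
    assoc <- phs_height_association(sub_cohort, phs)
    utils::write.table(assoc, file.path(config$out_dir, "phs_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact("prs", file.path(config$out_dir, "phs_association.tsv"))
    summary$prs <<- list(n_selected = nrow(sel),
                         pooled_beta = assoc$estimate[assoc$stratum == "all"])
    NULL
  })

  spath <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA)
  add_artifact("summary", spath)
  persist()
  invisible(list(manifest = manifest, summary = summary,
                 out_dir = config$out_dir))
}
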