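#' Default pipeline configuration
#'
#' All tunable parameters of a seeded end-to-end run, as a named list.
#' Override entries via [run_pipeline()]'s `...` or by editing the
#' returned list.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    window = 1000L,
    step = 100L,
    bin_width = 1000L,
    n = 50L,
    theta = 20,
    span_bp = 10000L,
    wf = list(N = 500L, L = 50000L, mu = 5e-7, r = 2e-6, s = 0.05, h = 0.5,
              sampling_freq = 1.0),
    null_reps = 50L,
    cutoffs = c(0.05, 0.1),
    top_fraction = 0.01,
    maf = 0.05,
    min_ehh = 0.05
  )
}

validate_config <- function(config) {
  if (config$window <= 0) abort("config error at $window: must be > 0")
  if (config$step <= 0) abort("config error at $step: must be > 0")
  if (config$null_reps < 2) abort("config error at $null_reps: must be >= 2")
  if (config$wf$s < 0) abort("config error at $wf$s: must be >= 0")
  invisible(config)
}

write_stage_tsv <- function(x, path, config, seed_used) {
  hdr <- c(
    sprintf("# sweepreg %s", as.character(utils::packageVersion("sweepreg"))),
    sprintf("# config_hash: %s", rlang::hash(config)),
    sprintf("# seed: %d", seed_used)
  )
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(path)
}

#' Seeded end-to-end pipeline run
#'
#' Simulates a swept locus, scans it (windowed diversity, iHS, CLR +
#' omega with a coalescent-calibrated null and the compound outlier
#' test), builds a regulatory-funnel fixture and runs the candidate
#' funnel, writing one TSV per stage into `out_dir`. Every output file
#' header carries the configuration hash and the seed, and rerunning
#' with the same configuration and seed reproduces the files byte for
#' byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A configuration list, see [default_config()].
#' @param ... Top-level config overrides (e.g. `seed = 7`).
#' @return Invisibly, a list with the per-stage tibbles (`diversity`,
#'   `ihs`, `compound`, `funnel`), the funnel `candidate`, and `files`.
#' @export
run_pipeline <- function(out_dir, config = default_config(), ...) {
  config <- utils::modifyList(config, list(...))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  wf <- config$wf
  sim <- simulate_wf(N = wf$N, L = wf$L, mu = wf$mu, r = wf$r, s = wf$s,
                     h = wf$h, sample_n = config$n,
                     sampling_freq = wf$sampling_freq, seed = seed)
  region <- genomic_interval("chr1", 1L, wf$L)
  inform(sprintf("stage simulate: %d chromosomes, %d segregating sites",
                 n_chrom(sim$hap), n_sites(sim$hap)))
  diversity <- windowed_scan(sim$hap, region, config$window, config$step)
  inform(sprintf("stage scan-diversity: %d windows", nrow(diversity)))
  ihs <- standardize_ihs(ihs_scan(sim$hap, min_ehh = config$min_ehh,
                                  maf = config$maf))
  inform(sprintf("stage ihs: %d scored sites", sum(ihs$valid)))
  null_sim <- function(i) {
    simulate_wf(N = wf$N, L = wf$L, mu = wf$mu, r = wf$r, s = 0, h = wf$h,
                sample_n = config$n, seed = seed + 1000L + i)$hap
  }
  clr_thr <- calibrate_null(function(h) max(clr_track(h, region,
                                                      config$bin_width)$clr,
                                            na.rm = TRUE),
                            null_sim, config$null_reps, config$cutoffs)
  omega_thr <- calibrate_null(function(h) {
    o <- omega_track(h, region, config$bin_width)$omega
    if (all(is.na(o))) NA_real_ else max(o, na.rm = TRUE)
  }, null_sim, config$null_reps, config$cutoffs)
  compound <- compound_test(clr_track(sim$hap, region, config$bin_width),
                            omega_track(sim$hap, region, config$bin_width),
                            clr_thr, omega_thr, config$top_fraction)
  inform(sprintf("stage sweep: %d bins, %d common outlier(s)",
                 nrow(compound), sum(compound$common_outlier)))
  fixture <- make_funnel_fixture(seed = seed)
  funnel <- run_funnel(fixture)
  candidate <- funnel$region_id[funnel$final_candidate]
  inform(sprintf("stage funnel: %d regions, candidate %s",
                 nrow(funnel), paste(candidate, collapse = ",")))
  files <- c(
    diversity = file.path(out_dir, "diversity.tsv"),
    ihs = file.path(out_dir, "ihs.tsv"),
    compound = file.path(out_dir, "compound.tsv"),
    funnel = file.path(out_dir, "funnel.tsv")
  )
  write_stage_tsv(diversity, files["diversity"], config, seed)
  write_stage_tsv(dplyr::select(ihs, !dplyr::any_of("reason")),
                  files["ihs"], config, seed)
  write_stage_tsv(compound, files["compound"], config, seed)
  write_stage_tsv(dplyr::select(funnel, -dplyr::any_of("accelerated")),
                  files["funnel"], config, seed)
  invisible(list(diversity = diversity, ihs = ihs, compound = compound,
                 funnel = funnel, candidate = candidate, sweep = sim$sweep,
                 files = files, config = config))
}
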