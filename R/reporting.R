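#' Deterministic base-case analysis
#'
#' Resolves every parameter to its base-case point, evaluates the full
#' multi-condition model and returns the strategy result together with the
#' ICER and per-condition breakdown. When `out_dir` is given, a summary
#' JSON and a per-condition CSV are written; every output embeds the
#' package version, seed (none for the deterministic run), draw count and
#' the parameter-set hash so runs are traceable.
#'
#' @param pset an `ahc_parameter_set`.
#' @param lt an unadjusted [life_table()].
#' @param rule base-case resolution rule, see [resolve_point()].
#' @param thresholds willingness-to-pay thresholds, GBP per QALY.
#' @param out_dir optional output directory.
#' @return list with `strategy` (an `ahc_strategy_result`), `icer`,
#'   `nmb` per threshold and `per_condition` data frame.
#' @export
run_base_case <- function(pset, lt = default_life_table(), rule = "midpoint",
                          thresholds = c(20000, 30000), out_dir = NULL) {
  params <- resolve_points(pset, rule)
  strategy <- evaluate_strategy(params, pset, lt)
  ic <- icer(strategy$inc_cost_total, strategy$inc_qaly_total)
  per_cond <- do.call(rbind, lapply(strategy$per_condition, function(x) {
    data.frame(condition = x$condition,
               pv_cost_ahc = x$pv_cost[["ahc"]],
               pv_cost_standard = x$pv_cost[["standard"]],
               pv_qaly_ahc = x$pv_qaly[["ahc"]],
               pv_qaly_standard = x$pv_qaly[["standard"]],
               inc_cost = x$inc_cost, inc_qaly = x$inc_qaly)
  }))
  out <- list(strategy = strategy, icer = ic,
              nmb = stats::setNames(
                nmb(strategy$inc_cost_total, strategy$inc_qaly_total,
                    thresholds), as.character(thresholds)),
              thresholds = thresholds, per_condition = per_cond)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- run_header(pset, seed = NA, n_draws = 0)
    write_summary_json(c(hdr, list(
      rule = rule, thresholds = thresholds,
      inc_cost = strategy$inc_cost_total,
      inc_qaly = strategy$inc_qaly_total,
      intervention_pv = strategy$intervention_pv,
      icer = ic$value, icer_flag = ic$flag, nmb = out$nmb)),
      file.path(out_dir, "base_case.json"))
    write_csv_header(per_cond, file.path(out_dir, "per_condition.csv"), hdr)
  }
  out
}

#' Write a PSA run to disk
#'
#' Draw-level CSV plus a summary JSON, both embedding the run header
#' (package version, seed, draw count, parameter hash).
#'
#' @param psa an `ahc_psa`.
#' @param pset the parameter set used for the run.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_psa <- function(psa, pset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- run_header(pset, seed = psa$seed, n_draws = psa$n_draws)
  s <- psa$summary
  write_summary_json(c(hdr, list(
    mean_inc_cost = s$mean_inc_cost, sd_inc_cost = s$sd_inc_cost,
    ci_inc_cost = s$ci_inc_cost,
    mean_inc_qaly = s$mean_inc_qaly, sd_inc_qaly = s$sd_inc_qaly,
    ci_inc_qaly = s$ci_inc_qaly,
    mean_icer = s$mean_icer, ci_icer = s$ci_icer,
    icer_excluded = s$icer_excluded,
    icer_ratio_of_means = s$icer_ratio_of_means,
    ceac = s$ceac)), file.path(out_dir, "psa_summary.json"))
  write_csv_header(psa$draws, file.path(out_dir, "psa_draws.csv"), hdr)
  invisible(file.path(out_dir, c("psa_summary.json", "psa_draws.csv")))
}

run_header <- function(pset, seed, n_draws) {
  list(package = "ahcmodel",
       version = as.character(utils::packageVersion("ahcmodel")),
       seed = seed, n_draws = n_draws,
       parameter_hash = parameter_hash(pset))
}

#' MD5 hash of a serialised parameter set
#' @param pset an `ahc_parameter_set`.
#' @return character MD5 digest.
#' @export
parameter_hash <- function(pset) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(write_parameter_set(pset), tmp)
  unname(tools::md5sum(tmp))
}

write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# CSV with commented header lines carrying run metadata
write_csv_header <- function(df, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr),
                     vapply(hdr, format, character(1))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
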