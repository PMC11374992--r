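#' Apply the registered exclusion rules
#'
#' Drops, in order: participants without consent, incomplete responses,
#' failed sound tests, failed attention checks, and surveys completed in
#' under `min_duration` seconds (video time excluded upstream). Each dropped
#' row is logged under the first rule it fails; nothing is dropped silently.
#'
#' @param raw data.frame with flag columns `consent`, `complete`, `sound_ok`,
#'   `attention_ok` (0/1) and `duration_s` (seconds).
#' @param min_duration minimum credible completion time in seconds.
#' @return list with `table` (the filtered rows) and `log` (named per-rule
#'   exclusion counts plus `retained`).
#' @export
apply_exclusions <- function(raw, min_duration = 90) {
  need <- c("consent", "complete", "sound_ok", "attention_ok", "duration_s")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    cm_stop(paste("missing flag columns:", paste(miss, collapse = ", ")),
            "schema_error")
  reasons <- with(raw, ifelse(
    consent == 0, "consent",
    ifelse(complete == 0, "incomplete",
           ifelse(sound_ok == 0, "sound",
                  ifelse(attention_ok == 0, "attention",
                         ifelse(duration_s < min_duration, "duration",
                                "retained"))))))
  log <- vapply(c("consent", "incomplete", "sound", "attention", "duration",
                  "retained"),
                function(r) sum(reasons == r), integer(1))
  list(table = raw[reasons == "retained", , drop = FALSE], log = log)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

boot_summary_list <- function(b) {
  b <- unclass(b)
  b$draws <- NULL
  b
}

manifest_for <- function(command, inputs, outputs, seed, B = NULL,
                         gates = NULL, extra = NULL) {
  c(list(command = command, inputs = inputs, outputs = outputs,
         seed = seed, B = B,
         package = "coolmediate",
         version = as.character(packageVersion("coolmediate")),
         gates_passed = if (is.null(gates)) NULL else
           all(unlist(gates$gates))),
    extra)
}

start_end_counts <- function(tab) {
  arms <- as.character(arm_label(tab$D, tab$C))
  start <- table(factor(arms, levels = ARM_LEVELS))
  passed <- if ("passed_checks" %in% names(tab))
    tab$passed_checks == 1 else rep(TRUE, nrow(tab))
  end <- table(factor(arms[passed], levels = ARM_LEVELS))
  list(start = setNames(as.integer(start), ARM_LEVELS),
       end = setNames(as.integer(end), ARM_LEVELS))
}

#' Run one pipeline stage
#'
#' Orchestrates the stages of a reproducible analysis run. Every stage
#' writes its artifacts plus a deterministic manifest (inputs, outputs,
#' seed, `B`, package version, gate outcome) to `out_dir`, so a stage can be
#' re-run identically from the manifest alone.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{generate a synthetic experiment from a `strata_config`;
#'     writes `participants.csv` and `strata_config.json`.}
#'   \item{score}{score a participant CSV; writes `scored.csv`.}
#'   \item{validate}{run the outcome-neutral gates on a scored CSV (start/end
#'     counts from the `passed_checks` flags); writes `validity.json`.}
#'   \item{analyze}{plug-in estimates, paired bootstrap of both effects and
#'     the registered decision report; writes `analysis.json` (and
#'     `draws.csv` when `write_draws`). Refuses to emit a decision report if
#'     a validity gate failed, unless `force = TRUE`; raises a documented
#'     not-implemented condition if the filler-effect check demands the
#'     alternative estimator, whose correction is out of scope here.}
#'   \item{power}{simulation-based power curve from a scored pilot CSV;
#'     writes `power.csv` and `power.json`.}
#'   \item{explore}{mediated-share decomposition and per-emotion/per-option
#'     contrasts; writes `explore.json`.}
#'   \item{report}{render `analysis.json` as a small human-readable text
#'     summary (`report.txt`), percentages to one decimal.}
#' }
#'
#' @param command one of `simulate`, `score`, `analyze`, `validate`, `power`,
#'   `explore`, `report`.
#' @param input input path (CSV for data stages, JSON for `report`).
#' @param out_dir output directory (created if needed).
#' @param config a `strata_config` (simulate) or `power_config` (power).
#' @param B bootstrap draws for `analyze`/`explore`.
#' @param seed integer seed recorded in every output.
#' @param econ_threshold economic-significance threshold.
#' @param force emit the decision report even when a validity gate failed.
#' @param write_draws also write the raw bootstrap draws as CSV (analyze).
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "score", "analyze",
                                     "validate", "power", "explore",
                                     "report"),
                         input = NULL, out_dir = ".", config = NULL,
                         B = 1000L, seed = 1L, econ_threshold = 0.03,
                         force = FALSE, write_draws = FALSE) {
  command <- match.arg(command)
  if (econ_threshold <= 0)
    cm_stop("econ_threshold must be positive", "invalid_argument")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  artifacts <- character()
  manifest <- NULL

  if (command == "simulate") {
    if (is.null(config)) config <- default_strata_config(seed = seed)
    config$seed <- as.integer(seed)
    tab <- simulate_experiment(config)
    write_participants(tab, p("participants.csv"))
    write_strata_config(config, p("strata_config.json"))
    artifacts <- c(p("participants.csv"), p("strata_config.json"))
    manifest <- manifest_for("simulate", character(), artifacts, seed,
                             extra = list(n_rows = nrow(tab)))
  } else if (command == "score") {
    tab <- read_participants(input)
    scored <- score_participants(tab)
    write.csv(scored, p("scored.csv"), row.names = FALSE, quote = FALSE)
    artifacts <- p("scored.csv")
    manifest <- manifest_for("score", input, artifacts, seed,
                             extra = list(n_in = nrow(tab),
                                          n_scored = nrow(scored)))
  } else if (command == "validate") {
    scored <- read_scored(input)
    cnt <- start_end_counts(scored)
    gates <- run_validity_gates(scored[keep_passed(scored), , drop = FALSE],
                                cnt$start, cnt$end)
    write_json_report(unclass(gates), p("validity.json"))
    artifacts <- p("validity.json")
    manifest <- manifest_for("validate", input, artifacts, seed,
                             gates = gates)
  } else if (command == "analyze") {
    scored <- read_scored(input)
    cnt <- start_end_counts(scored)
    scored <- scored[keep_passed(scored), , drop = FALSE]
    gates <- run_validity_gates(scored, cnt$start, cnt$end)
    if (gates$use_alternative_estimator)
      cm_stop(paste("the filler-effect check demands the alternative",
                    "estimator for a cool-off direct effect on donations,",
                    "which is not implemented"), "not_implemented")
    if (!all(unlist(gates$gates)) && !force)
      cm_stop(paste("a validity gate failed; the estimates carry little",
                    "weight (rerun with force = TRUE to emit anyway)"),
              "gates_failed")
    summ <- summarize_arms(scored)
    est <- estimate_mediated_effect(summ)
    eff <- bootstrap_effects(scored, B = B, seed = seed,
                             econ_threshold = econ_threshold)
    decision <- decide_hypotheses(eff$tt, eff$m, econ_threshold, gates)
    out <- list(arm_summaries = as.data.frame(summ),
                estimates = unclass(est),
                bootstrap_tt = boot_summary_list(eff$tt),
                bootstrap_m = boot_summary_list(eff$m),
                decision = unclass(decision)[
                  c("h1_rejected", "h2_rejected",
                    "h2_economically_insignificant", "h2_inconclusive",
                    "p_h1", "p_h2", "econ_threshold")],
                gates = unclass(gates))
    write_json_report(out, p("analysis.json"))
    artifacts <- p("analysis.json")
    if (write_draws) {
      write.csv(data.frame(delta_TT = eff$tt$draws, delta_M = eff$m$draws),
                p("draws.csv"), row.names = FALSE, quote = FALSE)
      artifacts <- c(artifacts, p("draws.csv"))
    }
    manifest <- manifest_for("analyze", input, artifacts, seed, B,
                             gates = gates)
  } else if (command == "power") {
    scored <- read_scored(input)
    if (is.null(config))
      cm_stop("power requires a power_config", "invalid_argument")
    config$seed <- as.integer(seed)
    curve <- simulate_power(scored[keep_passed(scored), , drop = FALSE],
                            config)
    write.csv(as.data.frame(curve), p("power.csv"), row.names = FALSE,
              quote = FALSE)
    write_json_report(list(config = unclass(config),
                           curve = as.data.frame(curve)),
                      p("power.json"))
    artifacts <- c(p("power.csv"), p("power.json"))
    manifest <- manifest_for("power", input, artifacts, seed, config$B)
  } else if (command == "explore") {
    scored <- read_scored(input)
    scored <- scored[keep_passed(scored), , drop = FALSE]
    eff <- bootstrap_effects(scored, B = B, seed = seed,
                             econ_threshold = econ_threshold)
    ms <- mediated_share(eff$tt$draws, eff$m$draws)
    out <- list(mediated_share = unclass(ms)[
      c("share_at_zero", "winsorized_fraction", "median", "pct_95",
        "ci_95", "n_excluded")],
      per_emotion = per_emotion_effects(scored),
      per_option = per_option_effects(scored))
    write_json_report(out, p("explore.json"))
    artifacts <- p("explore.json")
    manifest <- manifest_for("explore", input, artifacts, seed, B)
  } else if (command == "report") {
    an <- jsonlite::read_json(input, simplifyVector = TRUE)
    lines <- c(
      "Cooling-off mediation analysis",
      sprintf("Total effect: %+.1fpp (plug-in), 5th pct %+.1fpp, p = %.3f",
              100 * an$estimates$delta_TT, 100 * an$bootstrap_tt$pct_5,
              an$decision$p_h1),
      sprintf("Mediated effect: %+.1fpp (plug-in), q_hat = %.1f%%, p = %.3f",
              100 * an$estimates$delta_M, 100 * an$estimates$q_hat,
              an$decision$p_h2),
      sprintf("H1 %s; H2 %s%s",
              if (an$decision$h1_rejected) "rejected" else "not rejected",
              if (an$decision$h2_rejected) "rejected" else "not rejected",
              if (an$decision$h2_inconclusive) " (inconclusive)" else
                if (an$decision$h2_economically_insignificant)
                  " (economically insignificant)" else ""))
    writeLines(lines, p("report.txt"))
    artifacts <- p("report.txt")
    manifest <- manifest_for("report", input, artifacts, seed)
  }
  write_json_report(manifest, p(paste0("manifest_", command, ".json")))
  invisible(c(artifacts, p(paste0("manifest_", command, ".json"))))
}

keep_passed <- function(scored) {
  if ("passed_checks" %in% names(scored)) scored$passed_checks == 1
  else rep(TRUE, nrow(scored))
}

read_scored <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("D", "C", "donation_score", "neg_emotion_score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    cm_stop(paste("missing scored columns:", paste(miss, collapse = ", ")),
            "schema_error")
  tab
}
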