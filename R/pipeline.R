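# End-to-end pipeline: code raw survey CSVs, build the stigma table, run
# the three-model sequence per subgroup, and write deterministic artifacts
# (JSON at full precision, report tables rounded to 4 decimals).

#' Validate and normalize a pipeline configuration
#'
#' @param config Named list, or path to a YAML/JSON file holding one, with
#'   entries \code{respondents}, \code{laws}, \code{attitudes},
#'   \code{covariates} (input CSV paths), \code{output_dir}, and optionally
#'   \code{subgroups}, \code{probe_rule}, \code{probes}, \code{n_draws},
#'   \code{seed}, \code{digits}.
#' @return Validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    subgroups = c("sexual_minority_men", "sexual_minority_women",
                  "gender_minority"),
    probe_rule = "respondent", probes = NULL,
    n_draws = 10000, seed = 20240601L, digits = 4
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  needed <- c("respondents", "laws", "attitudes", "covariates", "output_dir")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    stop("pipeline config lacks entries: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("respondents", "laws", "attitudes", "covariates")) {
    if (!file.exists(config[[k]])) {
      stop("input path does not exist: ", config[[k]], " (", k, ")",
           call. = FALSE)
    }
  }
  structure(config, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

ci_list <- function(ci) {
  list(point = ci$point, lower = unname(ci$lower), upper = unname(ci$upper),
       level = ci$level, n_draws = ci$n_draws, seed = ci$seed,
       significant = ci$significant)
}

#' Serialize a mediation result to plain lists
#'
#' Full-precision representation of every derived quantity (rounding is a
#' report-layer concern only), suitable for JSON output.
#'
#' @param res \code{mediation_result}.
#' @return Nested list.
#' @export
mediation_result_json <- function(res) {
  meds <- lapply(res$mediators, function(m) {
    list(a = m$a, a_se = m$a_se, b = m$b, b_se = m$b_se,
         a_model3 = m$a_model3,
         a3 = m$a3, a3_se = m$a3_se, tau1_sq = m$tau1_sq,
         indirect = m$indirect, indirect_ci = ci_list(m$indirect_ci),
         indirect_variance = m$indirect_variance,
         indirect_sd = m$indirect_sd,
         index = m$index, index_ci = ci_list(m$index_ci),
         conditional = as.list(m$conditional),
         conditional_ci = lapply(m$conditional_ci, ci_list))
  })
  list(subgroup = res$subgroup, n_obs = res$n_obs,
       n_clusters = res$n_clusters,
       probes = as.list(res$probes),
       c_prime = res$c_prime, c_prime_se = res$c_prime_se,
       mediators = meds,
       lr_2v1 = unclass(res$lr_2v1), lr_3v2 = unclass(res$lr_3v2),
       logliks = res$logliks, converged = res$converged,
       seed = res$config$seed)
}

model_summary_frame <- function(res, digits = 4) {
  rows <- list()
  for (nm in names(res$mediators)) {
    m <- res$mediators[[nm]]
    rows[[length(rows) + 1]] <- data.frame(
      term = c(paste0("CP -> ", nm), paste0(nm, " -> Dep"),
               paste0("Int -> ", nm), paste0("Index (", nm, ")"),
               paste0("Indirect (", nm, ")")),
      estimate = round(c(m$a, m$b, m$a3, m$index, m$indirect), digits),
      se = c(round(m$a_se, digits), round(m$b_se, digits),
             round(m$a3_se, digits), NA, NA),
      stringsAsFactors = FALSE
    )
  }
  rows[[length(rows) + 1]] <- data.frame(
    term = c("CP -> Dep", "LR 2 vs 1 (df 4)", "LR 3 vs 2 (df 12)"),
    estimate = round(c(res$c_prime, res$lr_2v1$delta_chi2,
                       res$lr_3v2$delta_chi2), digits),
    se = c(round(res$c_prime_se, digits), NA, NA),
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

conditional_frame <- function(res, digits = 4) {
  out <- list()
  for (nm in names(res$mediators)) {
    m <- res$mediators[[nm]]
    for (p in names(res$probes)) {
      ci <- m$conditional_ci[[p]]
      out[[length(out) + 1]] <- data.frame(
        mediator = nm, probe = p,
        moderator_value = round(unname(res$probes[p]), digits),
        conditional_indirect = round(unname(m$conditional[p]), digits),
        lower = round(unname(ci$lower), digits),
        upper = round(unname(ci$upper), digits),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Codes the raw respondent CSV, builds the structural-stigma table from
#' the law/policy, attitude and covariate CSVs, assembles per-subgroup
#' analysis tables with listwise deletion, runs the three-model moderated
#' mediation sequence for each requested subgroup, and writes per-subgroup
#' JSON results, a compact model-summary TSV, a conditional-effect TSV, the
#' coding report and a run manifest to the output directory. Outputs are
#' deterministic under a fixed seed (no timestamps).
#'
#' @param config See \code{\link{pipeline_config}}; a list or a path.
#' @param dry_run Validate inputs and schemas only, fit nothing.
#' @return Invisibly, a list with \code{status} (0 on success, 1 when any
#'   model failed to converge), \code{results} (per-subgroup
#'   \code{mediation_result}s) and \code{paths} of written artifacts.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  config <- pipeline_config(config)
  raw <- utils::read.csv(config$respondents, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  laws <- utils::read.csv(config$laws, stringsAsFactors = FALSE)
  attitudes <- utils::read.csv(config$attitudes, stringsAsFactors = FALSE)
  covariates <- utils::read.csv(config$covariates, stringsAsFactors = FALSE)

  coded <- code_survey_data(raw)
  stigma <- build_stigma_table(laws, attitudes, covariates)
  if (dry_run) {
    return(invisible(list(status = 0, results = NULL, paths = character())))
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(name) {
    p <- file.path(config$output_dir, name)
    paths[[length(paths) + 1]] <<- p
    p
  }
  write_json_file(coded$report, emit("coding_report.json"))
  write_tsv(as.data.frame(stigma), emit("stigma_table.tsv"))

  results <- list()
  deletions <- list()
  status <- 0
  for (sg in config$subgroups) {
    tab <- build_analysis_table(coded$records, sg, stigma)
    deletions[[sg]] <- list(n_input = attr(tab, "n_input"),
                            n_dropped = attr(tab, "n_dropped"),
                            n_analyzed = nrow(tab))
    if (!nrow(tab)) next
    mc <- mediation_config(probe_rule = config$probe_rule,
                           probes = config$probes,
                           n_draws = config$n_draws,
                           seed = as.integer(config$seed))
    res <- run_sequence(tab, "stigma", mc)
    results[[sg]] <- res
    if (!all(res$converged)) status <- 1
    write_json_file(mediation_result_json(res),
                    emit(paste0(sg, "_result.json")))
    write_tsv(model_summary_frame(res, config$digits),
              emit(paste0(sg, "_models.tsv")))
    write_tsv(conditional_frame(res, config$digits),
              emit(paste0(sg, "_conditional.tsv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("stigmamed")),
    seed = config$seed, n_draws = config$n_draws,
    probe_rule = config$probe_rule,
    subgroups = config$subgroups,
    coding = coded$report[c("n_raw", "n_retained")],
    deletions = deletions,
    status = status
  )
  write_json_file(manifest, emit("manifest.json"))
  invisible(list(status = status, results = results, paths = unlist(paths)))
}
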