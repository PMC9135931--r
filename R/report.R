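# Human-readable run summaries and reproducibility manifests.

fmt_pct <- function(pct) {
  ifelse(
    is.na(pct), "n/a",
    sprintf("%s%d%%", ifelse(pct >= 0, "+", "-"), round(abs(pct)))
  )
}

#' Markdown summary of comparison (and correlation) results
#'
#' Per region, lists variables significant before FDR correction (raw
#' p < alpha, with star coding and percent change) and the variables
#' whose significance is sustained after Benjamini-Hochberg adjustment.
#' Deterministic: the same inputs always produce byte-identical text.
#'
#' @param comparison Output of [run_group_comparison()].
#' @param correlation Optional output of [run_age_correlation()].
#' @param alpha Raw-p threshold used for the pre-FDR lists.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(comparison, correlation = NULL, alpha = 0.05) {
  lines <- c("# Regional fatty-acid aging summary", "")
  lines <- c(lines, "## Middle-aged vs elderly comparison", "")
  for (rg in unique(comparison$region)) {
    sub <- comparison[comparison$region == rg, ]
    pre <- sub[!is.na(sub$p_raw) & sub$p_raw < alpha, ]
    post <- sub[sub$discovery %in% TRUE, ]
    lines <- c(lines, sprintf("### %s", rg), "")
    lines <- c(lines, sprintf(
      "- significant before FDR (p < %.2f): %s", alpha,
      if (nrow(pre)) {
        paste(sprintf(
          "%s (%s%s)", pre$variable, fmt_pct(pre$pct_change),
          ifelse(nzchar(pre$sig_flags), paste0(", ", pre$sig_flags), "")
        ), collapse = "; ")
      } else "none"
    ))
    lines <- c(lines, sprintf(
      "- sustained after FDR adjustment: %s",
      if (nrow(post)) paste(post$variable, collapse = "; ") else "none"
    ), "")
  }
  if (!is.null(correlation)) {
    lines <- c(lines, "## Age-continuum correlations", "")
    for (rg in unique(correlation$region)) {
      sub <- correlation[correlation$region == rg, ]
      pre <- sub[!is.na(sub$p_raw) & sub$p_raw < alpha, ]
      post <- sub[sub$discovery %in% TRUE, ]
      lines <- c(lines, sprintf("### %s", rg), "")
      lines <- c(lines, sprintf(
        "- correlated with age (p < %.2f): %s", alpha,
        if (nrow(pre)) {
          paste(
            sprintf("%s (rho = %.2f)", pre$variable, pre$rho),
            collapse = "; "
          )
        } else "none"
      ))
      lines <- c(lines, sprintf(
        "- sustained after FDR adjustment: %s",
        if (nrow(post)) paste(post$variable, collapse = "; ") else "none"
      ), "")
    }
  }
  lines
}

#' Write a markdown report
#'
#' @param lines Character vector from [report_markdown()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Build a reproducibility manifest
#'
#' Records the tool version, timestamp, configuration hash, input file
#' digests, seed and row counts of a run; reruns with an identical
#' manifest (minus the timestamp) reproduce identical outputs.
#'
#' @param config List of configuration values.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param seed Integer seed used, or `NULL`.
#' @param counts Named list of per-stage row counts.
#' @return List of class `"run_manifest"`.
#' @export
run_manifest <- function(config = list(), inputs = character(),
                         seed = NULL, counts = list()) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file), add = TRUE)
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  digests <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(existing))
  } else {
    list()
  }
  structure(
    list(
      tool = "lipidaging",
      version = as.character(utils::packageVersion("lipidaging")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config,
      config_md5 = unname(tools::md5sum(cfg_file)),
      inputs = digests,
      seed = seed,
      counts = counts
    ),
    class = "run_manifest"
  )
}

#' Write a manifest JSON sidecar
#'
#' @param manifest A [run_manifest()].
#' @param path Output path (conventionally `<output>.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    unclass(manifest), path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
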