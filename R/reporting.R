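## Volcano-plot tables and figures, signal summaries, run manifest.

#' Volcano-plot coordinates for one outcome x level x stage
#'
#' x is the base-2 logarithm of the hazard ratio, y the negative base-10
#' logarithm of the FDR-adjusted p value (discovery stage; the validation
#' stage, which carries no FDR adjustment, uses the raw p). p values are
#' floored at `p_floor` before the log to avoid infinities.
#'
#' @param results Rows of a screen report's `results` table for one
#'   outcome, level and stage.
#' @param q Significance level; a row is significant when its plotted p is
#'   `<= q` (boundary inclusive, matching [bh_adjust()]).
#' @param p_floor Lower bound applied to p before taking the log.
#' @return data.frame `drug`, `x`, `y`, `significant`, `direction`,
#'   sorted by `y` descending. Unconverged rows and non-positive hazard
#'   ratios are excluded (counted in attribute `n_excluded`).
#' @export
volcano_table <- function(results, q = 0.05, p_floor = 1e-300) {
  stopifnot(length(unique(results$stage)) <= 1)
  p <- ifelse(results$stage == "discovery", results$p_fdr_adjusted,
              results$p_raw)
  ok <- results$converged %in% TRUE & !is.na(results$hr) & results$hr > 0 &
    !is.na(p)
  excluded <- sum(!ok)
  r <- results[ok, , drop = FALSE]
  p <- pmax(p[ok], p_floor)
  out <- data.frame(drug = r$drug, x = log2(r$hr), y = -log10(p),
                    significant = p <= q,
                    direction = ifelse(r$hr < 1, "protective",
                                       "detrimental"))
  out <- out[order(-out$y, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

volcano_plot <- function(vt, title) {
  vt$significant <- factor(vt$significant, levels = c(FALSE, TRUE))
  ggplot2::ggplot(vt, ggplot2::aes(x = x, y = y, colour = significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "hazard ratio"),
                  y = expression(-log[10] ~ "adjusted p"),
                  title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write screen results, volcano tables/figures, signals and manifest
#'
#' Emits `results.csv` (full per-drug table), one
#' `volcano_<outcome>_L<level>_<stage>.csv` (and `.png` figure) per
#' combination present, `signals.csv` (validated signals with both-stage
#' hazard ratios), and `manifest.json` (configuration, seeds, package
#' version, row counts). All CSV output is deterministic given the same
#' report.
#'
#' @param report A `screen_report`.
#' @param out_dir Output directory (created if needed).
#' @param q Significance level for the volcano significance flag.
#' @param render_figures Render PNG volcano figures (default `TRUE`).
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(report, out_dir, q = report$config$fdr_q,
                          render_figures = TRUE) {
  stopifnot(inherits(report, "screen_report"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  written <- character(0)
  res <- report$results

  path <- file.path(out_dir, "results.csv")
  utils::write.csv(format_results(res), path, row.names = FALSE,
                   quote = FALSE)
  written <- c(written, path)

  if (nrow(res)) {
    combos <- unique(res[, c("outcome", "level", "stage")])
    for (i in seq_len(nrow(combos))) {
      sub <- res[res$outcome == combos$outcome[i] &
                   res$level == combos$level[i] &
                   res$stage == combos$stage[i], , drop = FALSE]
      vt <- volcano_table(sub, q = q)
      stem <- sprintf("volcano_%s_L%d_%s", combos$outcome[i],
                      combos$level[i], combos$stage[i])
      vpath <- file.path(out_dir, paste0(stem, ".csv"))
      utils::write.csv(vt, vpath, row.names = FALSE, quote = FALSE)
      written <- c(written, vpath)
      if (render_figures && nrow(vt)) {
        fig <- file.path(out_dir, paste0(stem, ".png"))
        ggplot2::ggsave(fig, volcano_plot(vt, stem), width = 6, height = 5,
                        dpi = 120)
        written <- c(written, fig)
      }
    }
  }

  spath <- file.path(out_dir, "signals.csv")
  utils::write.csv(report$validated_signals, spath, row.names = FALSE,
                   quote = FALSE)
  written <- c(written, spath)

  cfg <- report$config
  manifest <- list(
    package = "mwascreen",
    package_version = as.character(utils::packageVersion("mwascreen")),
    config = cfg[setdiff(names(cfg), NULL)],
    n_results = nrow(res),
    n_discovery_signals = nrow(report$discovery_signals),
    n_validated_signals = nrow(report$validated_signals))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mpath)
  invisible(written)
}

format_results <- function(res) {
  num <- vapply(res, is.numeric, logical(1)) &
    !names(res) %in% c("level", "n_users", "n_nonusers", "n_events")
  res[num] <- lapply(res[num], function(x) signif(x, 10))
  res
}
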