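#' Plot an enrichment random walk
#'
#' @param walk a [random_walk()] result.
#' @param ... passed to [plot()].
#' @export
plot_random_walk <- function(walk, ...) {
  plot(seq_len(walk$N), walk$running_sum, type = "l",
       xlab = "rank in correlation-ranked list", ylab = "running sum",
       main = sprintf("Enrichment walk (G = %d, ES = %.2f)", walk$G, walk$es),
       ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(walk$argmax, walk$es, pch = 19, col = 2)
  invisible(walk)
}

#' Plot enrichment score against set size
#'
#' @param scan a [scan_set_sizes()] result.
#' @param ... passed to [plot()].
#' @export
plot_es_curve <- function(scan, ...) {
  plot(scan$G, scan$es, type = "b", pch = 20,
       xlab = "set size G", ylab = "enrichment score", ...)
  graphics::abline(v = attr(scan, "best_G"), lty = 2, col = 2)
  invisible(scan)
}

#' Plot a ROC curve
#'
#' @param roc a data frame with `fpr`, `tpr` (from [roc_auc()]).
#' @param ... passed to [plot()].
#' @export
plot_roc <- function(roc, ...) {
  plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}

#' Plot training and validation error by pre-partitioning level
#'
#' @param curves a [level_curves()] result.
#' @param ... passed to [plot()].
#' @export
plot_level_curves <- function(curves, ...) {
  rng <- range(curves$train_omr, curves$valid_omr)
  plot(curves$level, curves$train_omr, type = "b", pch = 20, ylim = rng,
       xlab = "pre-partitioning level", ylab = "pooled OMR", ...)
  graphics::lines(curves$level, curves$valid_omr, type = "b", pch = 1, col = 2)
  graphics::legend("topright", c("training", "validation"),
                   col = c(1, 2), pch = c(20, 1), lty = 1, bty = "n")
  invisible(curves)
}

write_plots <- function(report, outdir) {
  png_to <- function(name, expr) {
    grDevices::png(file.path(outdir, name), width = 700, height = 500)
    on.exit(grDevices::dev.off())
    expr
  }
  ranked <- attr(report$enrichment, "ranked")
  png_to("walk.png", plot_random_walk(random_walk(ranked, report$best_set)))
  png_to("es_curve.png", plot_es_curve(report$enrichment))
  png_to("roc_oob.png", plot_roc(report$roc$oob,
                                 main = sprintf("OOB ROC (AUC %.3f)",
                                                report$auc$oob)))
  png_to("level_curves.png", plot_level_curves(report$level_curves))
  invisible(outdir)
}
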