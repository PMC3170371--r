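#' Adjust a set of p-values by several methods at once
#'
#' Runs any combination of SGoF, SGoF+, BH and Holm on the same p-values and
#' assembles the full per-test table: raw p-value, BH- and Holm-adjusted
#' p-values, discovery flags for the metatest methods, and the q-value under
#' the chosen pi0 estimator and epFDR variant. This is the table the `adjust`
#' command-line subcommand writes out.
#'
#' @param p Numeric vector of p-values (or a file path readable by
#'   [read_pvalues()]).
#' @param alpha Significance level for every method (default 0.05).
#' @param gamma Fixed threshold for SGoF (default `alpha`).
#' @param methods Methods to run, among `"sgof"`, `"sgof+"`, `"bh"`,
#'   `"holm"`.
#' @param gof Goodness-of-fit test choice for the metatests (see [sgof()]).
#' @param pi0_method Pi0 estimator feeding the q-values: `"smoothing"`
#'   (default, as in the reference q-value algorithm), `"bootstrap"`,
#'   `"lbe"`, `"sdpb"`, `"mode"` (modal aggregate of all four), or
#'   `"fixed"`.
#' @param pi0_fixed Value used when `pi0_method = "fixed"`.
#' @param robust Robust (`TRUE`, default) or standard epFDR variant.
#' @param seed Seed for the bootstrap pi0 estimator, if used.
#' @return List of class `"sgof_adjustment"` with elements `table` (per-test
#'   data frame in input order), `results` (per-method result objects),
#'   `pi0` (value used), `alpha`, `gamma`.
#' @export
adjust_pvalues <- function(p, alpha = 0.05, gamma = alpha,
                           methods = c("sgof", "sgof+", "bh", "holm"),
                           gof = c("auto", "binomial", "chi2"),
                           pi0_method = c("smoothing", "bootstrap", "lbe",
                                          "sdpb", "mode", "fixed"),
                           pi0_fixed = 1, robust = TRUE, seed = NULL) {
  if (is.character(p) && length(p) == 1L) p <- read_pvalues(p)
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  gof <- match.arg(gof)
  pi0_method <- match.arg(pi0_method)
  methods <- match.arg(methods, several.ok = TRUE)
  pi0_val <- switch(pi0_method,
    smoothing = pi0_smoothing(p)$value,
    bootstrap = pi0_bootstrap(p, seed = seed)$value,
    lbe = pi0_lbe(p)$value,
    sdpb = pi0_sdpb(p, alpha = alpha)$value,
    mode = pi0_all(p, alpha = alpha, seed = seed)$mode,
    fixed = pi0_fixed)
  qt <- qvalues(p, pi0 = pi0_val, robust = robust)
  tab <- data.frame(index = seq_along(p), p = p)
  results <- list()
  for (m in methods) {
    res <- switch(m,
      "sgof" = sgof(p, alpha = alpha, gamma = gamma, gof = gof),
      "sgof+" = sgof_plus(p, alpha = alpha, gof = gof),
      "bh" = bh_adjust(p, alpha = alpha),
      "holm" = holm_adjust(p, alpha = alpha))
    results[[m]] <- res
    if (m == "bh") tab$p_bh <- res$adjusted
    if (m == "holm") tab$p_holm <- res$adjusted
    flag <- logical(length(p))
    flag[res$rejected_indices] <- TRUE
    tab[[paste0("rejected_", sub("\\+", "_plus", m))]] <- flag
  }
  tab$epfdr <- qt$epfdr
  tab$qvalue <- qt$qvalue
  structure(list(table = tab, results = results, pi0 = pi0_val,
                 pi0_method = pi0_method, robust = robust,
                 alpha = alpha, gamma = gamma),
            class = "sgof_adjustment")
}

#' @export
print.sgof_adjustment <- function(x, ...) {
  cat(sprintf("multiple-testing adjustment of %d p-values (alpha = %g)\n",
              nrow(x$table), x$alpha))
  cat(sprintf("  pi0 (%s): %.4f, %s epFDR\n", x$pi0_method, x$pi0,
              if (x$robust) "robust" else "standard"))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    n <- if (!is.null(r$n_discoveries)) r$n_discoveries else length(r$rejected_indices)
    cat(sprintf("  %-6s %d discoveries\n", m, n))
  }
  invisible(x)
}

#' Write adjustment results to files
#'
#' Produces the two classic output files: a per-method list of selected tests
#' at the chosen level (`<prefix>_selected.tsv`), and the full per-test table
#' as TSV (`<prefix>_table.tsv`) and as a minimal standalone HTML table
#' (`<prefix>_table.html`).
#'
#' @param adj An [adjust_pvalues()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the character vector of files written.
#' @export
write_adjustment <- function(adj, prefix) {
  stopifnot(inherits(adj, "sgof_adjustment"))
  sel_path <- paste0(prefix, "_selected.tsv")
  tab_path <- paste0(prefix, "_table.tsv")
  html_path <- paste0(prefix, "_table.html")
  sel <- do.call(rbind, lapply(names(adj$results), function(m) {
    idx <- adj$results[[m]]$rejected_indices
    if (length(idx) == 0L) return(NULL)
    data.frame(method = m, index = idx, p = adj$table$p[idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(sel)) {
    sel <- data.frame(method = character(0), index = integer(0), p = numeric(0))
  }
  utils::write.table(sel, sel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(adj$table, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- adj$table
  fmt <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("<tr>", paste0("<td>", vapply(tab[i, ], format, character(1)),
                          "</td>", collapse = ""), "</tr>")
  }, character(1))
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>multiple-testing adjustment</title></head><body>",
    sprintf("<p>pi0 (%s) = %.4f; alpha = %g; %s epFDR</p>",
            adj$pi0_method, adj$pi0, adj$alpha,
            if (adj$robust) "robust" else "standard"),
    "<table border='1'>",
    paste0("<tr>", paste0("<th>", names(tab), "</th>", collapse = ""), "</tr>"),
    fmt,
    "</table></body></html>"), html_path)
  invisible(c(sel_path, tab_path, html_path))
}
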