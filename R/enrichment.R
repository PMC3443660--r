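#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up false discovery rate adjustment, order-preserving
#' with the input vector.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Centrality summary of the differential nodes
#'
#' Condenses where the differential nodes sit in the pathway's centrality
#' spectrum: minimum, median, 75th percentile and maximum of the *raw*
#' (unadjusted) centralities of the differential nodes. Quantiles use
#' linear interpolation between order statistics.
#'
#' @param weights A `weight_vector`.
#' @param diff_nodes Character vector of differential node ids (subset of
#'   the pathway's nodes).
#' @return Named numeric vector `c(min, median, q75, max)`; all `NA` when
#'   `diff_nodes` is empty.
#' @export
#' @examples
#' w <- weight_vector("demo", c(A = 1, B = 2, C = 3, D = 4))
#' diff_centrality_summary(w, c("A", "B", "C", "D"))  # 1 2.5 3.25 4
diff_centrality_summary <- function(weights, diff_nodes) {
  stopifnot(inherits(weights, "weight_vector"))
  diff_nodes <- unique(as.character(diff_nodes))
  if (!length(diff_nodes)) {
    return(c(min = NA_real_, median = NA_real_, q75 = NA_real_, max = NA_real_))
  }
  unknown <- setdiff(diff_nodes, names(weights$raw))
  if (length(unknown)) {
    stop("differential node(s) not in the pathway: ",
         paste(unknown, collapse = ", "))
  }
  v <- unname(weights$raw[diff_nodes])
  c(min = min(v),
    median = unname(stats::quantile(v, 0.5, type = 7)),
    q75 = unname(stats::quantile(v, 0.75, type = 7)),
    max = max(v))
}

#' Run centrality-weighted enrichment over a catalogue
#'
#' For every (pathway, measure) pair: computes the adjusted node weights,
#' maps the differential genes to differentially affected nodes, scores the
#' pathway, simulates the Bernoulli gene-perturbation null
#' ([simulate_null_scores()]) and takes the empirical p-value; finally
#' applies BH-FDR across pathways. FDR is computed within each measure by
#' default (each measure is its own family of tests).
#'
#' Per-pathway RNG streams are derived deterministically from the root seed
#' and the (pathway, measure) labels, so results do not depend on iteration
#' order. Pathways with no member genes at all cannot respond to the
#' differential list: they are reported with p = 1 and flagged.
#'
#' @param cat A [pathway_catalogue()].
#' @param profile A [differential_profile()].
#' @param measures Character vector of registered measure names.
#' @param reps Null-simulation repetitions per pathway (default 1000).
#' @param seed Optional integer root seed.
#' @param fdr_per_measure If `TRUE` (default) BH-FDR is applied within each
#'   measure; if `FALSE` a single correction spans all rows.
#' @return An `enrichment_table`: data frame with one row per
#'   (pathway, measure) — `pathway_id`, `measure`, `score`, `p_value`,
#'   `fdr`, `significant` (FDR <= 0.05), `n_nodes`, `n_diff_nodes`,
#'   `no_genes` flag, and `min`/`median`/`q75`/`max` of the differential
#'   nodes' raw centralities — sorted by (measure, p_value, pathway_id),
#'   with run metadata in attributes.
#' @export
run_enrichment <- function(cat, profile, measures = c("equal.weight"),
                           reps = 1000, seed = NULL,
                           fdr_per_measure = TRUE) {
  stopifnot(inherits(cat, "pathway_catalogue"),
            inherits(profile, "differential_profile"))
  if (!length(measures)) stop("'measures' must name at least one weight measure")
  unknown <- setdiff(measures, registered_measures())
  if (length(unknown)) {
    stop("unknown weight measure(s): ", paste(unknown, collapse = ", "),
         "; registered measures: ",
         paste(registered_measures(), collapse = ", "))
  }
  p_diff <- diff_probability(profile)

  rows <- list()
  for (pw in cat$pathways) {
    diff_nodes <- map_genes_to_nodes(pw, profile)
    no_genes <- length(pathway_genes(pw)) == 0L
    if (no_genes) {
      warning("pathway '", pw$pathway_id,
              "' has no member genes; reporting p = 1", call. = FALSE)
    }
    for (m in measures) {
      w <- compute_weights(pw, m)
      sc <- pathway_score(w, diff_nodes)
      if (no_genes) {
        p <- 1
      } else {
        stream <- if (is.null(seed)) NULL else
          derive_seed(seed, paste(pw$pathway_id, m, sep = "\r"))
        nd <- simulate_null_scores(pw, w, p_diff, reps = reps, seed = stream,
                                   observed = sc$score)
        p <- nd$p_value
      }
      cs <- diff_centrality_summary(w, diff_nodes)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pw$pathway_id, measure = m, score = sc$score,
        p_value = p, fdr = NA_real_, n_nodes = length(pw$nodes),
        n_diff_nodes = length(diff_nodes), no_genes = no_genes,
        min = cs[["min"]], median = cs[["median"]], q75 = cs[["q75"]],
        max = cs[["max"]], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (fdr_per_measure) {
    for (m in unique(tab$measure)) {
      i <- tab$measure == m
      tab$fdr[i] <- bh_fdr(tab$p_value[i])
    }
  } else {
    tab$fdr <- bh_fdr(tab$p_value)
  }
  tab$significant <- tab$fdr <= 0.05
  tab <- tab[order(match(tab$measure, measures), tab$p_value, tab$pathway_id), ]
  rownames(tab) <- NULL
  structure(tab, class = c("enrichment_table", "data.frame"),
            seed = seed, reps = reps, p_diff = p_diff,
            fdr_per_measure = fdr_per_measure)
}

#' Write an enrichment table as TSV
#'
#' Output begins with `#`-prefixed metadata lines recording the package
#' version, seed, repetitions and the conventions that the underlying
#' method leaves open (betweenness directed and unnormalized, the alpha
#' rule, the quantile convention), so a run is reproducible from its
#' output alone. p-values and FDRs are printed in scientific notation with
#' four significant digits.
#'
#' @param tab An `enrichment_table` from [run_enrichment()].
#' @param path Output file path.
#' @param extra Optional named character vector of additional metadata.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(tab, path, extra = NULL) {
  stopifnot(inherits(tab, "enrichment_table"))
  meta <- c(
    sprintf("# pathcent %s", as.character(utils::packageVersion("pathcent"))),
    sprintf("# seed=%s reps=%s p_diff=%s",
            format(attr(tab, "seed") %||% NA), format(attr(tab, "reps")),
            format(attr(tab, "p_diff"))),
    "# betweenness: directed, unnormalized, endpoints excluded",
    "# alpha: min non-zero raw weight / 100 (1 if all raw weights zero)",
    "# quantiles: linear interpolation between order statistics (type 7)",
    sprintf("# fdr: Benjamini-Hochberg, %s",
            if (isTRUE(attr(tab, "fdr_per_measure"))) "per measure" else "pooled")
  )
  if (!is.null(extra)) meta <- c(meta, sprintf("# %s=%s", names(extra), extra))
  out <- as.data.frame(tab)
  out$p_value <- formatC(out$p_value, format = "e", digits = 3)
  out$fdr <- formatC(out$fdr, format = "e", digits = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
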