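# Downstream statistics: hierarchical clustering of labeling profiles,
# FDR-controlled metabolite-metabolite correlation networks, hypergeometric
# pathway enrichment, and the false-positive-rate evaluation protocol.

#' Cluster labeling-extent profiles
#'
#' Hierarchically clusters metabolites by their labeling-extent time
#' profiles using correlation distance `1 - Pearson r` and the configured
#' linkage (`"ward.D"` or `"complete"`), cutting the tree into `n_clusters`
#' groups. Constant (zero-variance) profiles have no defined correlation;
#' they are held out of the tree and assigned afterwards to the cluster
#' whose centroid is nearest in Euclidean distance, flagged.
#'
#' @param le_matrix Numeric matrix, metabolites x time points, rownames =
#'   metabolite ids; no missing values.
#' @param linkage `"ward.D"` (default) or `"complete"`.
#' @param n_clusters Number of clusters (default 3).
#' @return Tibble `metabolite_id`, `cluster` (integer), `fallback`
#'   (logical: assigned by nearest centroid). Attribute `hclust` holds the
#'   tree.
#' @export
cluster_le_profiles <- function(le_matrix, linkage = c("ward.D", "complete"),
                                n_clusters = 3) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(le_matrix), nrow(le_matrix) >= 2, !anyNA(le_matrix))
  ids <- rownames(le_matrix) %||% as.character(seq_len(nrow(le_matrix)))
  vari <- apply(le_matrix, 1, sd) > 0
  if (sum(vari) < 2) {
    # fully degenerate: everything in one effective cluster
    warn("all profiles are constant or near-constant; clustering is degenerate")
    return(tibble(metabolite_id = ids, cluster = 1L, fallback = TRUE))
  }
  good <- le_matrix[vari, , drop = FALSE]
  cm <- cor(t(good))
  d <- stats::as.dist(1 - cm)
  hc <- hclust(d, method = linkage)
  k <- min(n_clusters, nrow(good))
  cl <- cutree(hc, k = k)
  out <- tibble(metabolite_id = ids[vari], cluster = as.integer(cl), fallback = FALSE)
  if (any(!vari)) {
    centroids <- do.call(rbind, map(seq_len(k), function(g) {
      colMeans(good[cl == g, , drop = FALSE])
    }))
    extra <- list_rbind(map(which(!vari), function(i) {
      dd <- map_dbl(seq_len(k), function(g) sqrt(sum((le_matrix[i, ] - centroids[g, ])^2)))
      tibble(metabolite_id = ids[i], cluster = which.min(dd), fallback = TRUE)
    }))
    out <- bind_rows(out, extra)
  }
  out <- out[match(ids, out$metabolite_id), ]
  attr(out, "hclust") <- hc
  out
}

#' Pearson correlation p-value (t transform)
#'
#' Two-sided p-value of a Pearson correlation from the exact t transform
#' with `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient(s).
#' @param n Sample size.
#' @return p-value(s).
#' @export
cor_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

#' Metabolite-metabolite correlation network
#'
#' Computes all pairwise Pearson correlations of labeling extents across
#' samples, converts them to two-sided p-values, applies Benjamini-Hochberg
#' FDR adjustment over all pairs, and keeps edges with adjusted p below
#' `alpha`. Zero-variance metabolites are excluded from the pair universe
#' and reported.
#'
#' @param le Data frame or matrix, samples x metabolites (column names =
#'   metabolite ids), e.g. labeling extents at the final labeling time.
#' @param alpha FDR threshold (default 0.05).
#' @return Object of class `tracer_network`: list with `edges` (tibble
#'   `metabolite_a`, `metabolite_b`, `r`, `p`, `p_adj`, `kept`), `nodes`,
#'   `alpha`, `n_samples`.
#' @export
correlation_network <- function(le, alpha = 0.05) {
  m <- as.matrix(le)
  stopifnot(nrow(m) >= 3)
  if (is.null(colnames(m))) colnames(m) <- paste0("M", seq_len(ncol(m)))
  keep <- apply(m, 2, sd) > 0
  if (any(!keep)) {
    inform(sprintf("correlation network: excluded %d zero-variance metabolite(s): %s",
                   sum(!keep), paste(colnames(m)[!keep], collapse = ", ")))
  }
  m <- m[, keep, drop = FALSE]
  p <- ncol(m)
  if (p < 2) {
    out <- list(edges = tibble(metabolite_a = character(), metabolite_b = character(),
                               r = numeric(), p = numeric(), p_adj = numeric(),
                               kept = logical()),
                nodes = colnames(m), alpha = alpha, n_samples = nrow(m))
    class(out) <- "tracer_network"
    return(out)
  }
  cm <- cor(m)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  pv <- cor_pvalue(r, nrow(m))
  padj <- p.adjust(pv, method = "BH")
  edges <- tibble(
    metabolite_a = colnames(m)[ut[, 1]],
    metabolite_b = colnames(m)[ut[, 2]],
    r = r, p = pv, p_adj = padj, kept = padj < alpha
  )
  out <- list(edges = edges, nodes = colnames(m), alpha = alpha, n_samples = nrow(m))
  class(out) <- "tracer_network"
  out
}

#' @export
print.tracer_network <- function(x, ...) {
  cat(sprintf("<tracer_network> %d nodes, %d/%d edges kept at FDR < %g (n = %d samples)\n",
              length(x$nodes), sum(x$edges$kept), nrow(x$edges), x$alpha, x$n_samples))
  invisible(x)
}

#' @export
tidy.tracer_network <- function(x, ...) {
  filter(x$edges, .data$kept)
}

#' @export
glance.tracer_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_pairs = nrow(x$edges),
         n_edges = sum(x$edges$kept), alpha = x$alpha, n_samples = x$n_samples)
}

#' @export
autoplot.tracer_network <- function(object, ...) {
  ed <- tidy(object)
  nodes <- tibble(metabolite_id = object$nodes)
  nodes$angle <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  nodes$x <- cos(nodes$angle); nodes$y <- sin(nodes$angle)
  ed <- ed |>
    left_join(rename(nodes[, c("metabolite_id", "x", "y")], xa = "x", ya = "y"),
              by = c(metabolite_a = "metabolite_id")) |>
    left_join(rename(nodes[, c("metabolite_id", "x", "y")], xb = "x", yb = "y"),
              by = c(metabolite_b = "metabolite_id"))
  ggplot() +
    geom_segment(data = ed, aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                                yend = .data$yb, colour = .data$r), alpha = 0.6) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y)) +
    labs(colour = "Pearson r") +
    theme_minimal()
}

#' Hypergeometric pathway enrichment
#'
#' Over-representation of a metabolite selection in each pathway:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with background size
#' `N`, pathway size `K` (restricted to the background), selection size
#' `n`, and `k` hits. Pathways with no background members are omitted.
#'
#' @param selection Character vector of selected metabolite ids (must be a
#'   subset of `background`).
#' @param pathway_map Tibble `pathway_id`, `metabolite_id`.
#' @param background Character vector of background metabolite ids.
#' @return Tibble `pathway_id`, `hits`, `pathway_size`, `selection_size`,
#'   `background_size`, `p_value`, sorted by `p_value`.
#' @export
hypergeometric_enrichment <- function(selection, pathway_map, background) {
  selection <- unique(selection)
  background <- unique(background)
  if (length(setdiff(selection, background))) {
    abort("selection must be a subset of the background",
          class = "tracerkit_validation_error")
  }
  pm <- pathway_map |>
    filter(.data$metabolite_id %in% background) |>
    distinct(.data$pathway_id, .data$metabolite_id)
  N <- length(background)
  n <- length(selection)
  out <- pm |>
    group_by(.data$pathway_id) |>
    summarise(hits = sum(.data$metabolite_id %in% selection),
              pathway_size = dplyr::n(), .groups = "drop") |>
    mutate(selection_size = n, background_size = N,
           p_value = phyper(.data$hits - 1, .data$pathway_size,
                            N - .data$pathway_size, n, lower.tail = FALSE))
  arrange(out[out$pathway_size > 0, ], .data$p_value)
}

#' False-positive-rate evaluation on unlabeled samples
#'
#' Runs the false-positive protocol on a MID table from unlabeled samples
#' only: an isotopologue (other than M0) with labeled fraction above
#' `threshold` in any one sample is a false positive; the
#' isotopologue-level FPR is the share of false-positive isotopologues
#' among all non-M0 isotopologues. The metabolite-level FPR is the share of
#' extracted metabolites called labeled under the standard majority rule.
#'
#' @param mids MID tibble of unlabeled runs (`metabolite_id`,
#'   `isotopologue_index`, `run_id`, `labeled_fraction`).
#' @param threshold Fraction threshold (default 0.02).
#' @return Tibble with `level` (isotopologue/metabolite), `false_positives`,
#'   `total`, `fpr`.
#' @export
evaluate_fpr <- function(mids, threshold = 0.02) {
  if (is.null(mids) || !nrow(mids)) {
    abort("empty MID table", class = "tracerkit_validation_error")
  }
  iso <- mids |>
    filter(.data$isotopologue_index > 0) |>
    group_by(.data$metabolite_id, .data$isotopologue_index) |>
    summarise(fp = any(.data$labeled_fraction > threshold), .groups = "drop")
  calls <- call_labeled(mids, threshold = threshold)
  tibble(
    level = c("isotopologue", "metabolite"),
    false_positives = c(sum(iso$fp), sum(calls$metabolites$labeled)),
    total = c(nrow(iso), nrow(calls$metabolites)),
    fpr = c(mean(iso$fp), mean(calls$metabolites$labeled))
  )
}
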