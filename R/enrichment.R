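# Ontology enrichment statistics: one-sided Fisher's exact test with
# hypergeometric Z-scores, Haldane-corrected odds ratios with Woolf 95%
# confidence intervals, and Benjamini-Hochberg FDR.

#' Define the testing universe and filter the input gene list
#'
#' The default universe is every gene carrying at least one (propagated)
#' annotation in the ontology; alternatively a custom background can be
#' supplied.  Input genes outside the universe are dropped (a count is
#' logged to stderr).
#'
#' @param input_genes Character vector of gene symbols.
#' @param ont An `xgr_ontology`.
#' @param mode `"annotated"` (default) or `"custom"`.
#' @param custom_universe Character vector of background genes when
#'   `mode = "custom"`.
#' @param propagated Use propagated (`TRUE`, default) or direct annotations.
#' @return List with `universe` (sorted character) and `input` (filtered,
#'   sorted character).
#' @export
make_universe <- function(input_genes, ont, mode = c("annotated", "custom"),
                          custom_universe = NULL, propagated = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ont, "xgr_ontology"))
  input_genes <- unique(as.character(input_genes))
  ann <- if (propagated) ont$propagated else ont$direct
  if (mode == "annotated") {
    universe <- sort(unique(unlist(ann, use.names = FALSE)))
  } else {
    if (is.null(custom_universe))
      stop("mode 'custom' requires custom_universe", call. = FALSE)
    universe <- sort(unique(as.character(custom_universe)))
  }
  input <- sort(intersect(input_genes, universe))
  dropped <- length(input_genes) - length(input)
  if (dropped > 0)
    xgr_log("universe: dropped %d input gene(s) outside the %d-gene universe",
            dropped, length(universe))
  if (length(input) == 0)
    stop("no input genes in universe", call. = FALSE)
  list(universe = universe, input = input)
}

#' One-sided (enrichment) Fisher's exact test p-value
#'
#' Upper-tail hypergeometric probability of observing an overlap of `k` or
#' more between an input list of size `n` and a term of size `K` within a
#' universe of `N` genes.  Vectorized over its arguments.
#'
#' @param k Overlap count.
#' @param K Term size within the universe.
#' @param n Input size within the universe.
#' @param N Universe size.
#' @return P-values in `(0, 1]`.
#' @export
#' @examples
#' fisher_one_sided(3, 3, 3, 10)  # 1/choose(10,3)
fisher_one_sided <- function(k, K, n, N) {
  check_table(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_table <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 1))
    stop("invalid contingency counts", call. = FALSE)
  if (any(k > pmin(K, n)) || any(K > N) || any(n > N) || any(N - K - n + k < 0))
    stop("contingency table cells must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Hypergeometric Z-score of an overlap
#'
#' Standardizes the overlap `k` by the exact null moments of the
#' hypergeometric distribution: `mu = nK/N`,
#' `sigma^2 = nK(N-K)(N-n) / (N^2 (N-1))`.  Degenerate tables
#' (`sigma = 0`) return 0.
#'
#' @inheritParams fisher_one_sided
#' @return Z-scores (vectorized).
#' @export
hypergeom_zscore <- function(k, K, n, N) {
  check_table(k, K, n, N)
  if (any(N < 2)) stop("N must be >= 2", call. = FALSE)
  k <- as.numeric(k); K <- as.numeric(K); n <- as.numeric(n); N <- as.numeric(N)
  mu <- n * K / N
  sigma2 <- n * K * (N - K) * (N - n) / (N^2 * (N - 1))
  z <- ifelse(sigma2 > 0, (k - mu) / sqrt(sigma2), 0)
  as.numeric(z)
}

#' Odds ratio with Woolf confidence interval
#'
#' Sample odds ratio of the 2x2 enrichment table with cells
#' `a = k, b = K - k, c = n - k, d = N - K - n + k`.  If any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells; both the odds
#' ratio and the Woolf logit interval use the corrected cells.
#'
#' @inheritParams fisher_one_sided
#' @param level Confidence level (default 0.95).
#' @return Data.frame with columns `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(k, K, n, N, level = 0.95) {
  check_table(k, K, n, N)
  a <- k; b <- K - k; c <- n - k; d <- N - K - n + k
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(odds_ratio = or,
             ci_low = exp(log(or) - zq * se),
             ci_high = exp(log(or) + zq * se))
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Ontology enrichment of a gene list
#'
#' For each term whose propagated annotation within the universe has size in
#' `[min_term, max_term]` and whose overlap with the input is at least
#' `min_overlap`, computes the one-sided Fisher p-value, hypergeometric
#' Z-score, Haldane/Woolf odds ratio and CI, and BH FDR across the tested
#' terms.  Results are sorted by (fdr, pvalue, -zscore, term_id).
#'
#' @param input_genes Character vector of gene symbols.
#' @param ont An `xgr_ontology` (propagate first for hierarchical ontologies).
#' @param min_term,max_term Term-size filter applied within the universe
#'   (defaults 10 and 2000).
#' @param min_overlap Minimum overlap to test a term (default 3).
#' @param universe_mode `"annotated"` or `"custom"` (see [make_universe()]).
#' @param custom_universe Background genes for `universe_mode = "custom"`.
#' @param propagated Use propagated annotations (default `TRUE`).
#' @param fdr_scope `"tested"` (default): BH across tested terms only;
#'   `"filtered"`: BH across all size-filtered terms, untested ones counting
#'   as p = 1.
#' @return Data.frame of class `xgr_enrichment` with columns `term_id`,
#'   `name`, `k`, `K`, `n`, `N`, `zscore`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `pvalue`, `fdr`, `members` (comma-joined overlapping genes).
#' @export
run_enrichment <- function(input_genes, ont, min_term = 10, max_term = 2000,
                           min_overlap = 3,
                           universe_mode = c("annotated", "custom"),
                           custom_universe = NULL, propagated = TRUE,
                           fdr_scope = c("tested", "filtered")) {
  universe_mode <- match.arg(universe_mode)
  fdr_scope <- match.arg(fdr_scope)
  uv <- make_universe(input_genes, ont, universe_mode, custom_universe,
                      propagated)
  universe <- uv$universe
  input <- uv$input
  N <- length(universe)
  n <- length(input)
  ann <- if (propagated) ont$propagated else ont$direct

  empty <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), zscore = numeric(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pvalue = numeric(0),
                      fdr = numeric(0), members = character(0),
                      stringsAsFactors = FALSE)

  term_sets <- lapply(ann, intersect, universe)
  Ks <- lengths(term_sets)
  sized <- names(term_sets)[Ks >= min_term & Ks <= max_term]
  if (length(sized) == 0) {
    xgr_log("enrichment: no terms of size %d-%d within the universe",
            min_term, max_term)
    return(structure(empty, class = c("xgr_enrichment", "data.frame")))
  }
  overlaps <- lapply(term_sets[sized], intersect, input)
  ks <- lengths(overlaps)
  tested <- sized[ks >= min_overlap]
  if (length(tested) == 0) {
    xgr_log("enrichment: no term reaches the minimum overlap of %d",
            min_overlap)
    return(structure(empty, class = c("xgr_enrichment", "data.frame")))
  }

  k <- unname(ks[tested])
  K <- unname(Ks[tested])
  p <- fisher_one_sided(k, K, n, N)
  z <- hypergeom_zscore(k, K, n, N)
  orci <- odds_ratio_ci(k, K, n, N)
  if (fdr_scope == "tested") {
    fdr <- bh_fdr(p)
  } else {
    p_all <- rep(1, length(sized))
    p_all[match(tested, sized)] <- p
    fdr <- bh_fdr(p_all)[match(tested, sized)]
  }
  res <- data.frame(
    term_id = tested,
    name = ont$terms$name[match(tested, ont$terms$term_id)],
    k = k, K = K, n = n, N = N,
    zscore = z,
    odds_ratio = orci$odds_ratio, ci_low = orci$ci_low,
    ci_high = orci$ci_high,
    pvalue = p, fdr = fdr,
    members = vapply(overlaps[tested],
                     function(g) paste(sort(g), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  res <- res[order(res$fdr, res$pvalue, -res$zscore, res$term_id), ]
  rownames(res) <- NULL
  xgr_log("enrichment: tested %d/%d size-filtered terms (n=%d, N=%d)",
          length(tested), length(sized), n, N)
  structure(res, class = c("xgr_enrichment", "data.frame"))
}

#' Write an enrichment table as TSV (optionally mirrored as JSON)
#'
#' @param res Result of [run_enrichment()].
#' @param path Output TSV path.
#' @param json Optional JSON mirror path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path, json = NULL) {
  write_tsv_file(res, path)
  if (!is.null(json))
    jsonlite::write_json(res, json, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  invisible(path)
}
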