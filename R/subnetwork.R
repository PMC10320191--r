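# Gene subnetwork identification: node scores become prizes x - lambda, a
# prize-collecting Steiner tree heuristic extracts a connected high-scoring
# tree, lambda is tuned by bisection to hit a desired subnetwork size, and
# significance comes from a degree-preserving node permutation test.

#' Build node scores from gene-level p-values
#'
#' `x = min(-log10(p), 16)`; the cap guards against infinite scores from
#' p-values that underflow to 0.
#'
#' @param genes Character vector of gene symbols.
#' @param pvalues Numeric p-values aligned with `genes`.
#' @return Named numeric vector of scores.
#' @export
scores_from_pvalues <- function(genes, pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  x <- pmin(-log10(pvalues), 16)
  x[is.na(x)] <- 0
  setNames(as.numeric(x), genes)
}

#' Assign prizes to network nodes
#'
#' Every network node gets prize `x - lam`; nodes without an input score use
#' `x = 0` (pure connectors).  Scored genes absent from the network are
#' dropped with a logged count.
#'
#' @param scores Named numeric vector of node scores (`x >= 0`).
#' @param net An `xgr_network`.
#' @param lam Penalty `lambda >= 0`.
#' @return Named numeric prize vector over `net$nodes`.
#' @export
assign_prizes <- function(scores, net, lam = 0) {
  stopifnot(lam >= 0)
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("scores must be finite and >= 0", call. = FALSE)
  x <- setNames(rep(0, length(net$nodes)), net$nodes)
  known <- intersect(names(scores), net$nodes)
  x[known] <- scores[known]
  off <- length(setdiff(names(scores), net$nodes))
  if (off > 0)
    xgr_log("prizes: %d scored gene(s) absent from the network were dropped",
            off)
  x - lam
}

new_subnetwork <- function(nodes, edges, objective, lambda = NA_real_) {
  structure(list(nodes = nodes, edges = edges, objective = objective,
                 lambda_final = lambda, empirical_p = NA_real_,
                 permutations_used = NA_integer_,
                 target_n = NA_integer_, tol = NA_integer_,
                 max_iter = NA_integer_, trace = NULL),
            class = "xgr_subnetwork")
}

#' @export
print.xgr_subnetwork <- function(x, ...) {
  cat(sprintf("xgr_subnetwork: %d nodes, %d edges, objective %.4g, lambda %.4g",
              length(x$nodes), nrow(x$edges), x$objective, x$lambda_final))
  if (!is.na(x$empirical_p))
    cat(sprintf(", empirical p %.4g (B=%d)", x$empirical_p,
                x$permutations_used))
  cat("\n")
  invisible(x)
}

#' Prize-collecting Steiner tree heuristic
#'
#' Seeds are nodes with positive prize.  Within each connected component the
#' tree grows from the highest-prize seed, repeatedly attaching the seed
#' with the cheapest shortest-path connection (path cost = average negative
#' prize of the endpoints of each edge, plus a tiny epsilon), after which
#' the optimal connected subtree of the merged tree is extracted by dynamic
#' programming.  The per-component tree with the largest prize sum is
#' returned; with no seeds the subnetwork is empty.
#'
#' @param net An `xgr_network` (must have at least one node).
#' @param prizes Named numeric prize vector over `net$nodes`
#'   (see [assign_prizes()]).
#' @param eps Epsilon added to every edge cost (default `1e-6`).
#' @return An `xgr_subnetwork`: `nodes` (sorted character), `edges`
#'   (data.frame `gene_a`, `gene_b`, `weight`), `objective` (sum of prizes
#'   over the returned nodes).
#' @export
pcst_heuristic <- function(net, prizes, eps = 1e-6) {
  if (length(net$nodes) == 0) stop("empty network", call. = FALSE)
  nodes <- net$nodes  # already sorted: index order == lexicographic order
  pr <- prizes[nodes]
  if (anyNA(pr)) stop("prizes must cover every network node", call. = FALSE)
  ia <- match(net$edges$gene_a, nodes)
  ib <- match(net$edges$gene_b, nodes)
  res <- .pcst_tm(length(nodes), ia - 1L, ib - 1L, as.numeric(pr), eps)
  sel <- nodes[res$nodes]
  em <- res$edges
  if (nrow(em) > 0) {
    ea <- pmin(nodes[em[, 1]], nodes[em[, 2]])
    eb <- pmax(nodes[em[, 1]], nodes[em[, 2]])
    key <- paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")
    w <- net$edges$weight[match(paste(ea, eb, sep = "\r"), key)]
    ed <- data.frame(gene_a = ea, gene_b = eb, weight = w,
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$gene_a, ed$gene_b), ]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(gene_a = character(0), gene_b = character(0),
                     weight = numeric(0), stringsAsFactors = FALSE)
  }
  new_subnetwork(sel, ed, res$objective)
}

#' Search for a subnetwork of a desired size
#'
#' Bisection on the prize penalty `lambda` over `[0, max(x)]`: larger
#' `lambda` shrinks the tree.  Stops when the subnetwork size is within
#' `tol` of `target_n` or after `max_iter` bisection steps, returning the
#' iterate whose size is closest to `target_n` (ties: larger objective, then
#' smaller `lambda`).
#'
#' @param net An `xgr_network`.
#' @param scores Named numeric node scores (`x >= 0`).
#' @param target_n Desired number of subnetwork genes.
#' @param tol Size tolerance (default `max(1, ceiling(0.1 * target_n))`).
#' @param max_iter Maximum bisection steps (default 50).
#' @return An `xgr_subnetwork` with `lambda_final` set and the bisection
#'   trace (data.frame `lambda`, `size`, `objective`) in `$trace`.
#' @export
search_subnetwork <- function(net, scores, target_n,
                              tol = max(1, ceiling(0.1 * target_n)),
                              max_iter = 50) {
  if (target_n < 1) stop("target_n must be >= 1", call. = FALSE)
  if (target_n > length(net$nodes)) {
    warning("target_n exceeds the number of network nodes; returning the ",
            "lambda = 0 solution", call. = FALSE)
    sub <- pcst_heuristic(net, assign_prizes(scores, net, 0))
    sub$lambda_final <- 0
    sub <- set_search_params(sub, target_n, tol, max_iter)
    sub$trace <- data.frame(lambda = 0, size = length(sub$nodes),
                            objective = sub$objective)
    return(sub)
  }
  # indexed fast path: tree reconstruction is deferred to the selected iterate
  x <- assign_prizes(scores, net, 0)
  nodes <- net$nodes
  ia <- match(net$edges$gene_a, nodes) - 1L
  ib <- match(net$edges$gene_b, nodes) - 1L
  lams <- numeric(0); sizes <- integer(0); objs <- numeric(0)
  eval_lambda <- function(lam) {
    res <- .pcst_tm(length(nodes), ia, ib, as.numeric(x) - lam, 1e-6)
    lams <<- c(lams, lam)
    sizes <<- c(sizes, length(res$nodes))
    objs <<- c(objs, res$objective)
    length(res$nodes)
  }
  lo <- 0; hi <- max(max(x), 0)
  done <- abs(eval_lambda(lo) - target_n) <= tol
  if (!done && hi > lo) {
    done <- abs(eval_lambda(hi) - target_n) <= tol
    iter <- 0
    while (!done && iter < max_iter) {
      mid <- (lo + hi) / 2
      sz <- eval_lambda(mid)
      if (abs(sz - target_n) <= tol) break
      if (sz > target_n) lo <- mid else hi <- mid
      iter <- iter + 1
    }
  }
  ord <- order(abs(sizes - target_n), -objs, lams)
  best_lam <- lams[ord[1]]
  best <- pcst_heuristic(net, x - best_lam)
  best$lambda_final <- best_lam
  best <- set_search_params(best, target_n, tol, max_iter)
  tr <- data.frame(lambda = lams, size = sizes, objective = objs)
  best$trace <- tr[order(tr$lambda), ]
  rownames(best$trace) <- NULL
  best
}

set_search_params <- function(sub, target_n, tol, max_iter) {
  sub$target_n <- as.integer(target_n)
  sub$tol <- as.integer(tol)
  sub$max_iter <- as.integer(max_iter)
  sub
}

#' Degree-preserving permutation significance of a subnetwork
#'
#' Network nodes are binned by degree quantiles; node scores are shuffled
#' within bins (preserving the score-hubness relationship under the null)
#' and the full size-targeted search is re-run per permutation.  The
#' empirical p-value is `(1 + #{null objective >= observed}) / (1 + B)`.
#'
#' @param net An `xgr_network`.
#' @param scores Named numeric node scores used for the observed subnetwork.
#' @param observed The observed [search_subnetwork()] result (its
#'   `target_n`, `tol` and `max_iter` are reused).
#' @param B Number of permutations (default 100).
#' @param bins Number of degree-quantile bins (default 10; fewer when there
#'   are fewer distinct degrees).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return The `observed` subnetwork with `empirical_p`,
#'   `permutations_used` and `null_objectives` filled in.
#' @export
permutation_significance <- function(net, scores, observed, B = 100,
                                     bins = 10, seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  stopifnot(inherits(observed, "xgr_subnetwork"), !is.na(observed$target_n))
  x <- assign_prizes(scores, net, 0)  # full score vector over nodes
  deg <- igraph::degree(as_igraph(net))[net$nodes]
  bin <- degree_bins(deg, bins)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  null_obj <- numeric(B)
  for (b in seq_len(B)) {
    xp <- x
    for (g in split(seq_along(x), bin))
      if (length(g) > 1) xp[g] <- x[sample(g)]
    names(xp) <- net$nodes
    sub <- search_subnetwork(net, xp, observed$target_n, observed$tol,
                             observed$max_iter)
    null_obj[b] <- sub$objective
  }
  observed$empirical_p <- (1 + sum(null_obj >= observed$objective)) / (1 + B)
  observed$permutations_used <- as.integer(B)
  observed$null_objectives <- null_obj
  observed
}

degree_bins <- function(deg, bins) {
  bins <- max(1, min(bins, length(unique(deg))))
  if (bins == 1) return(rep(1L, length(deg)))
  br <- unique(quantile(deg, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(deg)))
  as.integer(cut(deg, breaks = br, include.lowest = TRUE))
}

#' Write subnetwork node/edge tables and a JSON summary
#'
#' @param sub An `xgr_subnetwork`.
#' @param scores The node scores used (for the node table's `x` column).
#' @param net The source network.
#' @param nodes_path,edges_path,summary_path Output paths.
#' @param significance Optional named vector of input significance values
#'   (e.g. p-values) added as a node colour column.
#' @param seed Seed recorded in the summary.
#' @return `summary_path`, invisibly.
#' @export
write_subnetwork <- function(sub, scores, net, nodes_path, edges_path,
                             summary_path, significance = NULL, seed = NA) {
  x <- assign_prizes(scores, net, 0)
  nd <- data.frame(gene = sub$nodes,
                   x = unname(x[sub$nodes]),
                   prize = unname(x[sub$nodes]) - sub$lambda_final,
                   is_seed = unname(x[sub$nodes]) - sub$lambda_final > 0,
                   stringsAsFactors = FALSE)
  if (!is.null(significance))
    nd$significance <- unname(significance[sub$nodes])
  write_tsv_file(nd, nodes_path)
  write_tsv_file(sub$edges, edges_path)
  jsonlite::write_json(
    list(n_nodes = length(sub$nodes), n_edges = nrow(sub$edges),
         objective = sub$objective, lambda_final = sub$lambda_final,
         empirical_p = sub$empirical_p,
         permutations = sub$permutations_used, seed = seed),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(summary_path)
}
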