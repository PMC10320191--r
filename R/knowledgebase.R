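# Loading, validation and indexing of the plain-text knowledge resources:
# ontologies (GMT + optional DAG), gene networks, LD panels and
# entity-to-gene evidence datasets.

#' Load a gene-set ontology from a GMT file
#'
#' Each line is `term_id<TAB>description<TAB>gene1<TAB>gene2...`.  Lines
#' starting with `#` are ignored.  The result is a flat ontology (no DAG
#' edges); attach hierarchy with [attach_dag()] and propagate annotations
#' with [propagate_annotations()].
#'
#' @param path Path to a GMT file.
#' @return An object of class `xgr_ontology` with components `terms`
#'   (data.frame `term_id`, `name`), `direct` (named list term -> character
#'   vector of genes), `dag` (data.frame `child`, `parent`), `propagated`
#'   (named list term -> genes; equals `direct` until propagation) and
#'   `gene2term` (named list gene -> terms, from direct annotations).
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("T1\tfirst\tA\tB\tA", "T2\tsecond\tB\tC"), gmt)
#' ont <- load_gmt(gmt)
#' ont$propagated$T1
load_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop("malformed GMT line ", bad, " in ", path,
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  term_id <- vapply(fields, `[[`, character(1), 1)
  name <- vapply(fields, `[[`, character(1), 2)
  if (anyDuplicated(term_id))
    stop("duplicate term_id in GMT: ", term_id[duplicated(term_id)][1],
         call. = FALSE)
  direct <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  names(direct) <- term_id
  ont <- structure(
    list(terms = data.frame(term_id = term_id, name = name,
                            stringsAsFactors = FALSE),
         direct = direct,
         dag = data.frame(child = character(0), parent = character(0),
                          stringsAsFactors = FALSE),
         propagated = direct,
         gene2term = invert_annotations(direct)),
    class = "xgr_ontology")
  ont
}

invert_annotations <- function(term2gene) {
  if (length(term2gene) == 0) return(list())
  genes <- unlist(term2gene, use.names = FALSE)
  terms <- rep(names(term2gene), lengths(term2gene))
  lapply(split(terms, genes), function(x) sort(unique(x)))
}

#' @export
print.xgr_ontology <- function(x, ...) {
  cat(sprintf("xgr_ontology: %d terms, %d DAG edges, %d annotated genes\n",
              nrow(x$terms), nrow(x$dag), length(x$gene2term)))
  invisible(x)
}

#' Attach a term DAG to an ontology
#'
#' @param ont An `xgr_ontology`.
#' @param edges A data.frame (or 2-column matrix) of `(child, parent)` term
#'   pairs, or a path to a TSV with those two columns.
#' @return The ontology with `dag` set (annotations are NOT re-propagated;
#'   call [propagate_annotations()]).
#' @export
attach_dag <- function(ont, edges) {
  stopifnot(inherits(ont, "xgr_ontology"))
  if (is.character(edges) && length(edges) == 1)
    edges <- read_tsv_file(edges, c("child", "parent"),
                           col_classes = c("character", "character"))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    names(edges)[1:2] <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    known <- ont$terms$term_id
    unknown <- setdiff(unique(c(edges$child, edges$parent)), known)
    if (length(unknown) > 0)
      stop("DAG references unknown term(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    edges <- unique(edges[, c("child", "parent")])
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- find_one_cycle(edges)
      stop("term hierarchy contains a cycle: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
  } else {
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
  }
  ont$dag <- edges
  ont
}

# depth-first search for one directed cycle, for the error message
find_one_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return()
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      i <- match(v, path)
      res <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (u in adj[[v]]) visit(u)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(edges$child)) {
    visit(v)
    if (!is.null(res)) break
  }
  res
}

#' Propagate annotations up the term hierarchy (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' ancestor of that term: `propagated[parent] = direct[parent] U
#' propagated[children]`.  Idempotent; on a flat ontology it is the identity.
#'
#' @param ont An `xgr_ontology` (DAG attached, possibly empty).
#' @return The ontology with `propagated` and `gene2term` updated.
#' @export
propagate_annotations <- function(ont) {
  stopifnot(inherits(ont, "xgr_ontology"))
  prop <- ont$direct
  if (nrow(ont$dag) > 0) {
    g <- igraph::graph_from_data_frame(
      ont$dag, directed = TRUE,
      vertices = data.frame(name = ont$terms$term_id))
    # edges point child -> parent, so topological order lists children first
    ord <- names(igraph::topo_sort(g, mode = "out"))
    children <- split(ont$dag$child, ont$dag$parent)
    for (t in ord) {
      kids <- children[[t]]
      if (length(kids) > 0)
        prop[[t]] <- sort(unique(c(prop[[t]], unlist(prop[kids], use.names = FALSE))))
    }
  }
  ont$propagated <- prop
  ont$gene2term <- invert_annotations(prop)
  ont
}

# ---------------------------------------------------------------------------
# gene networks

TIER_THRESHOLDS <- c(highest = 0.9, high = 0.7, medium = 0.4)

tier_threshold <- function(tier, threshold = NULL) {
  if (identical(tier, "custom")) {
    if (is.null(threshold) || !is.numeric(threshold) || threshold < 0 || threshold > 1)
      stop("tier 'custom' requires a numeric threshold in [0,1]", call. = FALSE)
    return(threshold)
  }
  if (!tier %in% names(TIER_THRESHOLDS))
    stop("unknown confidence tier: ", tier,
         " (use highest/high/medium/custom)", call. = FALSE)
  unname(TIER_THRESHOLDS[tier])
}

new_network <- function(edges, tier) {
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 tier = tier),
            class = "xgr_network")
}

#' @export
print.xgr_network <- function(x, ...) {
  cat(sprintf("xgr_network (%s): %d nodes, %d edges\n",
              x$tier, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonicalize an edge table: gene_a < gene_b, no self-loops, duplicates
# collapsed keeping the maximum weight
canonical_edges <- function(df) {
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  keep <- a != b
  df <- data.frame(gene_a = a[keep], gene_b = b[keep],
                   weight = df$weight[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  w <- tapply(df$weight, key, max)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$weight <- as.numeric(w[paste(out$gene_a, out$gene_b, sep = "\r")])
  out
}

#' Load a weighted gene network from a TSV edge list
#'
#' Rows are `gene_a<TAB>gene_b<TAB>weight` with weights in `[0, 1]`
#' (functional-interaction confidence).  Edges below the tier threshold are
#' dropped, self-loops removed, duplicate edges collapsed keeping the maximum
#' weight, and endpoints stored in lexicographic order.
#'
#' @param path TSV path.
#' @param tier One of `"highest"` (>= 0.9), `"high"` (>= 0.7), `"medium"`
#'   (>= 0.4) or `"custom"`.
#' @param threshold Numeric threshold in `[0, 1]`, required when
#'   `tier = "custom"`.
#' @return An `xgr_network` (components `edges`, `nodes`, `tier`).
#' @export
load_network <- function(path, tier = "high", threshold = NULL) {
  df <- read_tsv_file(path, c("gene_a", "gene_b", "weight"),
                      col_classes = c("character", "character", "character"))
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) stop("non-numeric edge weight at line ",
                     which(is.na(w))[1], " of ", path, call. = FALSE)
  if (any(w < 0 | w > 1)) stop("edge weight outside [0,1] at line ",
                               which(w < 0 | w > 1)[1], " of ", path,
                               call. = FALSE)
  df$weight <- w
  thr <- tier_threshold(tier, threshold)
  n0 <- nrow(df)
  df <- df[df$weight >= thr, , drop = FALSE]
  xgr_log("network %s: kept %d/%d edges at tier %s (weight >= %g)",
          basename(path), nrow(df), n0, tier, thr)
  new_network(canonical_edges(df), tier)
}

#' Merge individual pathway edge sets into one gene network
#'
#' Mirrors the construction of a pathway-interaction network where every
#' pathway contributes its internal edges and the union forms the network.
#' Unweighted pathway edges default to weight 1.
#'
#' @param pathways A list of data.frames with columns `gene_a`, `gene_b` and
#'   optionally `weight`.
#' @return An `xgr_network` with tier `"custom"`.
#' @export
merge_pathway_networks <- function(pathways) {
  if (length(pathways) == 0)
    return(new_network(data.frame(gene_a = character(0), gene_b = character(0),
                                  weight = numeric(0), stringsAsFactors = FALSE),
                       "custom"))
  dfs <- lapply(pathways, function(p) {
    p <- as.data.frame(p, stringsAsFactors = FALSE)
    names(p)[1:2] <- c("gene_a", "gene_b")
    if (!"weight" %in% names(p)) p$weight <- 1.0
    p[, c("gene_a", "gene_b", "weight")]
  })
  merged <- do.call(rbind, dfs)
  new_network(canonical_edges(merged), "custom")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# ---------------------------------------------------------------------------
# LD panels and evidence datasets

#' Load a linkage-disequilibrium panel
#'
#' TSV rows `seed<TAB>proxy<TAB>r2[<TAB>proxy_chrom<TAB>proxy_pos]`; the
#' optional coordinate columns place proxies on the genome so that
#' proximity/interval linking can use them.
#'
#' @param path TSV path.
#' @param population Free-text population tag recorded on the panel.
#' @return An `xgr_ld_panel`: data.frame `seed`, `proxy`, `r2`,
#'   `proxy_chrom`, `proxy_pos` with attribute `population`.
#' @export
load_ld_panel <- function(path, population = "unspecified") {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 3) stop("LD panel needs >= 3 columns: seed, proxy, r2",
                          call. = FALSE)
  df <- data.frame(seed = as.character(raw[[1]]), proxy = as.character(raw[[2]]),
                   r2 = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  if (anyNA(df$r2) || any(df$r2 < 0 | df$r2 > 1))
    stop("LD r2 values must be numeric in [0,1]", call. = FALSE)
  if (ncol(raw) >= 5) {
    df$proxy_chrom <- as.character(raw[[4]])
    df$proxy_pos <- as.integer(raw[[5]])
  } else {
    df$proxy_chrom <- NA_character_
    df$proxy_pos <- NA_integer_
  }
  structure(df, class = c("xgr_ld_panel", "data.frame"),
            population = population)
}

#' Load a gene TSS table for proximity linking
#'
#' TSV rows `gene<TAB>chrom<TAB>tss<TAB>strand` (1-based TSS position).
#' @param path TSV path.
#' @return Data.frame with class `xgr_tss`.
#' @export
load_tss <- function(path) {
  df <- read_tsv_file(path, c("gene", "chrom", "tss", "strand"))
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$tss <- as.integer(df$tss)
  if (any(!nzchar(df$gene))) stop("empty gene symbol in TSS table", call. = FALSE)
  if (anyNA(df$tss) || any(df$tss < 1))
    stop("TSS positions must be integers >= 1", call. = FALSE)
  structure(df, class = c("xgr_tss", "data.frame"), kind = "proximity")
}

#' Load an interval-to-gene evidence dataset (PCHi-C or ABC enhancer maps)
#'
#' TSV rows `chrom<TAB>start<TAB>end<TAB>gene<TAB>strength` with 0-based
#' half-open intervals and non-negative interaction strengths.
#'
#' @param path TSV path.
#' @param kind `"pchic"` or `"abc"`.
#' @return Data.frame with class `xgr_interval_evidence` and attribute `kind`.
#' @export
load_interval_evidence <- function(path, kind = c("pchic", "abc")) {
  kind <- match.arg(kind)
  df <- read_tsv_file(path, c("chrom", "start", "end", "gene", "strength"))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$gene <- as.character(df$gene)
  df$strength <- as.numeric(df$strength)
  if (any(!nzchar(df$gene))) stop("empty gene symbol in ", path, call. = FALSE)
  if (any(df$start >= df$end))
    stop("interval with start >= end at line ",
         which(df$start >= df$end)[1], " of ", path, call. = FALSE)
  if (anyNA(df$strength) || any(df$strength < 0))
    stop("strengths must be non-negative numbers in ", path, call. = FALSE)
  structure(df, class = c("xgr_interval_evidence", "data.frame"), kind = kind)
}

#' Load a SNP-to-gene QTL evidence dataset (eQTL or pQTL)
#'
#' TSV rows `rsid<TAB>gene<TAB>weight` with weights in `(0, 1]` (e.g. a
#' normalized QTL significance).
#'
#' @param path TSV path.
#' @param kind `"eqtl"` or `"pqtl"`.
#' @return Data.frame with class `xgr_qtl_evidence` and attribute `kind`.
#' @export
load_qtl_evidence <- function(path, kind = c("eqtl", "pqtl")) {
  kind <- match.arg(kind)
  df <- read_tsv_file(path, c("rsid", "gene", "weight"))
  df$rsid <- as.character(df$rsid)
  df$gene <- as.character(df$gene)
  df$weight <- as.numeric(df$weight)
  if (any(!nzchar(df$gene))) stop("empty gene symbol in ", path, call. = FALSE)
  if (anyNA(df$weight) || any(df$weight <= 0 | df$weight > 1))
    stop("QTL weights must lie in (0,1] in ", path, call. = FALSE)
  structure(df, class = c("xgr_qtl_evidence", "data.frame"), kind = kind)
}
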