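#' Read a gene-set collection in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>member1<TAB>...`.
#'
#' @param path Path to the GMT file.
#' @param background Protein universe to intersect members with; when
#'   `NULL` the union of all members is used. Sets empty after
#'   intersection are dropped.
#' @return List with `sets` (named list of member vectors), `names`
#'   (set descriptions) and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT file")
  descs <- vapply(parts, function(p) if (length(p) >= 2) p[[2L]] else "",
                  character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids; names(descs) <- ids
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  sets <- lapply(sets, intersect, y = background)
  keep <- lengths(sets) > 0
  if (!all(keep)) sets <- sets[keep]
  list(sets = sets, names = descs[names(sets)], background = background)
}

#' Fisher overrepresentation analysis
#'
#' One-sided Fisher exact (hypergeometric upper tail) test of each gene
#' set for overrepresentation among the query proteins, with fold
#' enrichment `(a/k) / (K/M)` where `a` is the overlap, `k` the query
#' size, `K` the set size and `M` the background size. BH-adjusted
#' across sets; a set is reported iff `q < fdr` and
#' `fold_enrichment > min_fold`.
#'
#' @param daps Query protein set (e.g. the DAPs of one stratum); ids
#'   outside the background are dropped with a warning.
#' @param collection Result of [read_gmt()] (or a compatible list).
#' @param fdr FDR threshold (default 0.01).
#' @param min_fold Fold-enrichment threshold (default 2).
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"`.
#' @return Data frame `set_id, name, a, k, K, M, fold_enrichment, p, q,
#'   reported` sorted by p.
#' @export
fisher_ora <- function(daps, collection, fdr = 0.01, min_fold = 2,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(daps)) stop("empty query set")
  if (!length(collection$sets)) stop("empty gene-set collection")
  bg <- collection$background
  outside <- setdiff(daps, bg)
  if (length(outside)) {
    warning(length(outside), " query ids outside the background dropped")
    daps <- intersect(daps, bg)
  }
  M <- length(bg); k <- length(daps)
  rows <- lapply(names(collection$sets), function(sid) {
    set <- collection$sets[[sid]]
    K <- length(set)
    a <- length(intersect(daps, set))
    fold <- if (k > 0 && K > 0) (a / k) / (K / M) else 0
    p <- if (alternative == "greater") {
      stats::phyper(a - 1L, K, M - K, k, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(a, K - a, k - a, M - K - k + a), 2L),
                         alternative = "two.sided")$p.value
    }
    data.frame(set_id = sid,
               name = unname(collection$names[sid]),
               a = a, k = k, K = K, M = M,
               fold_enrichment = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$reported <- out$q < fdr & out$fold_enrichment > min_fold
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
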