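#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: set name, description, then member genes.
#' Duplicate members within a set are collapsed; duplicate set names are an
#' error; malformed lines are reported with their line number.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d: need name, description and >= 1 gene", i)
    nm <- f[1]
    if (nm %in% names(sets)) stopf("duplicate set name '%s' (line %d)", nm, i)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  structure(sets, class = "gene_set_collection", descriptions = desc)
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (a `gene_set_collection`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    nm <- names(sets)[i]
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[nm] else "na"
    paste(c(nm, d, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overrepresentation analysis of one gene list
#'
#' For every set the overlap `k` with the gene list is tested with the
#' hypergeometric upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, m)` (computed in stable log space via
#' [stats::phyper()]), where `N` is the universe size, `K` the set size
#' within the universe and `m` the list size.  `expect = m * K / N` and
#' `ratio = k / expect` (0 when `k = 0`) follow the WebGestalt conventions.
#' FDR is BH across the collection; rows are sorted by p.
#'
#' @param gene_list character vector of genes (genes outside the universe
#'   are dropped with a warning).
#' @param collection a `gene_set_collection`.
#' @param universe background gene universe (e.g. all genes on the
#'   expression platform after preprocessing).
#' @return an `enrichment_result` data frame with columns `set`,
#'   `set_size`, `list_size`, `universe_size`, `overlap`, `expect`,
#'   `ratio`, `p_value`, `fdr`.
#' @export
hypergeometric_ora <- function(gene_list, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warnf("%d gene(s) outside the universe dropped from the list", length(outside))
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  m <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    expect <- m * K / N
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, list_size = m, universe_size = N,
               overlap = k, expect = expect,
               ratio = if (k == 0) 0 else k / expect,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), set_size = integer(0),
                      list_size = integer(0), universe_size = integer(0),
                      overlap = integer(0), expect = numeric(0),
                      ratio = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
  } else {
    out$fdr <- bh_adjust(out$p_value)
    out <- out[order(out$p_value, out$set), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Enrichment battery over per-hub gene lists
#'
#' Runs [hypergeometric_ora()] for every hub's coexpressed gene list
#' (FDR computed within each list's battery, one family per hub) and
#' returns the concatenated rows passing the FDR cutoff, sorted by p.
#'
#' @param gene_lists a `coexpression_selection` or named list of character
#'   vectors (per-hub gene lists).
#' @param collection a `gene_set_collection`.
#' @param universe background universe shared by lists and sets.
#' @param fdr_cut significance cutoff on the per-list BH FDR (default 0.05).
#' @return data frame with a leading `hub` column plus the
#'   `enrichment_result` columns, significant rows only.
#' @export
run_enrichment_battery <- function(gene_lists, collection, universe, fdr_cut = 0.05) {
  if (inherits(gene_lists, "coexpression_selection")) {
    gene_lists <- lapply(unclass(gene_lists), function(d) d$gene)
  }
  rows <- lapply(names(gene_lists), function(h) {
    genes <- gene_lists[[h]]
    if (!length(genes) || !length(collection)) return(NULL)
    res <- hypergeometric_ora(genes, collection, universe)
    res <- res[res$fdr < fdr_cut, , drop = FALSE]
    if (!nrow(res)) return(NULL)
    cbind(hub = h, res, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(hub = character(0), set = character(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), overlap = integer(0),
                      expect = numeric(0), ratio = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$hub, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
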