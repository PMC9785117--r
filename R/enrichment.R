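#' Read a pathway library in GMT format
#'
#' GMT dialect: one pathway per line, tab-separated — name, description,
#' then member identifiers. Duplicate members within a pathway are
#' collapsed; the library universe is the union of all members.
#'
#' @param path path to a GMT file.
#' @return An object of class `pathway_library`: list with `pathways`
#'   (named list of character vectors) and `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  pathways <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": need name, description and at ",
           "least one member", call. = FALSE)
    }
    nm <- f[1]
    if (nm %in% names(pathways)) {
      stop("malformed GMT line ", i, ": duplicate pathway name '", nm, "'",
           call. = FALSE)
    }
    pathways[[nm]] <- unique(f[-(1:2)])
  }
  structure(list(pathways = pathways,
                 universe = sort(unique(unlist(pathways)))),
            class = "pathway_library")
}

#' Bundled synthetic pathway library
#'
#' A small hand-built metabolite-set library shipped with the package for
#' examples, tests and the synthetic pipeline. It is a synthetic stand-in
#' assembled from textbook pathway memberships (BCAA degradation, urea
#' cycle, ammonia recycling and common distractor pathways), not a copy of
#' any hosted database.
#'
#' @return A [pathway_library][read_gmt()].
#' @export
aging_pathway_library <- function() {
  read_gmt(system.file("extdata", "aging_pathways_synthetic.gmt",
                       package = "metaboaging", mustWork = TRUE))
}

#' Over-representation analysis of a metabolite set
#'
#' For each pathway, counts the hits (query members in the pathway) and
#' tests over-representation with the upper-tail hypergeometric probability
#' `P(X >= hits)` for a population of `universe_size` metabolites containing
#' `pathway_size` successes and `query_size` draws. The enrichment ratio is
#' observed hits over expected hits
#' (`query_size * pathway_size / universe_size`). P-values are
#' Benjamini-Hochberg adjusted across pathways. Query members absent from
#' the library universe cannot map and are dropped (their count is reported
#' in the `dropped` attribute), mirroring unidentified compounds in real
#' queries.
#'
#' @param query character vector of metabolite identifiers.
#' @param library a [pathway_library][read_gmt()].
#' @return data.frame of class `enrichment_result`, sorted by `p_hyper`:
#'   `pathway`, `hits`, `pathway_size`, `query_size`, `universe_size`,
#'   `expected`, `enrichment_ratio`, `p_hyper`, `p_fdr`, `hit_members`.
#' @export
ora_test <- function(query, library) {
  stopifnot(inherits(library, "pathway_library"))
  query <- unique(query)
  mapped <- intersect(query, library$universe)
  dropped <- length(query) - length(mapped)
  if (!length(mapped)) {
    stop("no query members map to the library universe", call. = FALSE)
  }
  N <- length(library$universe)
  n <- length(mapped)
  res <- lapply(names(library$pathways), function(pw) {
    members <- library$pathways[[pw]]
    K <- length(members)
    hit <- intersect(mapped, members)
    k <- length(hit)
    data.frame(
      pathway = pw, hits = k, pathway_size = K, query_size = n,
      universe_size = N, expected = n * K / N,
      enrichment_ratio = k / (n * K / N),
      p_hyper = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      hit_members = paste(sort(hit), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  res$p_fdr <- stats::p.adjust(res$p_hyper, method = "BH")
  res <- res[order(res$p_hyper, res$pathway), ]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("enrichment_result", "data.frame")
  res
}
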