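#' Term-to-gene annotation table
#'
#' GO-style or disease-style annotations: each term annotates a nonempty
#' gene set drawn from a stated gene universe.
#'
#' @param terms data frame with columns `term_id`, `term_name`,
#'   `namespace` (e.g. BP/MF/CC or "disease"), `gene`.
#' @param universe character vector of gene symbols; every annotated gene
#'   must belong to it.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(terms, universe) {
  need <- c("term_id", "term_name", "namespace", "gene")
  miss <- setdiff(need, names(terms))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  universe <- unique(as.character(universe))
  out <- terms[, need]
  bad <- setdiff(out$gene, universe)
  if (length(bad))
    stop(length(bad), " annotated gene(s) not in the universe",
         call. = FALSE)
  structure(list(terms = out, universe = universe),
            class = "annotation_table")
}

#' Read annotations from delimited text
#'
#' Either a 4-column GAF-like TSV (`term_id`, `term_name`, `namespace`,
#' `gene_symbol`) or a 2-column gene-disease TSV (`disease`,
#' `gene_symbol`), in which case the disease name doubles as term id and
#' the namespace is `"disease"`.
#'
#' @param path file path.
#' @param universe gene universe; defaults to the annotated genes.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, universe = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("term_id", "term_name", "namespace", "gene_symbol") %in%
          names(df))) {
    terms <- data.frame(term_id = df$term_id, term_name = df$term_name,
                        namespace = df$namespace, gene = df$gene_symbol,
                        stringsAsFactors = FALSE)
  } else if (ncol(df) == 2) {
    terms <- data.frame(term_id = df[[1]], term_name = df[[1]],
                        namespace = "disease", gene = df[[2]],
                        stringsAsFactors = FALSE)
  } else stop("unrecognized annotation format in ", path, call. = FALSE)
  annotation_table(terms, universe %||% unique(terms$gene))
}

#' Binary overrepresentation test
#'
#' For every term, tests whether the query list contains more of the
#' term's genes than expected from a uniform draw of the same size from
#' the universe: the hypergeometric upper tail `P(X >= k)` with `k` query
#' hits, `K` universe hits, query size `n` and universe size `N`.
#' Benjamini-Hochberg q-values are computed within each namespace.
#'
#' @param query gene list; genes outside the universe are dropped (count
#'   via `message`).
#' @param table an [annotation_table()].
#' @return Data frame, one row per term, with `term_id`, `term_name`,
#'   `namespace`, `k`, `K`, `n`, `N`, `ratio` (`"k/K"`), `p`, `q`; sorted
#'   by `p`.
#' @export
overrepresentation_test <- function(query, table) {
  stopifnot(inherits(table, "annotation_table"))
  query <- unique(as.character(query))
  out_of_universe <- setdiff(query, table$universe)
  if (length(out_of_universe))
    message(length(out_of_universe), " query gene(s) outside the universe dropped")
  query <- intersect(query, table$universe)
  if (!length(query))
    stop("query list empty after universe filtering", call. = FALSE)
  N <- length(table$universe)
  n <- length(query)
  split_terms <- split(table$terms$gene,
                       paste(table$terms$term_id, table$terms$term_name,
                             table$terms$namespace, sep = "\r"))
  keys <- do.call(rbind, strsplit(names(split_terms), "\r", fixed = TRUE))
  k <- vapply(split_terms, function(g) length(intersect(g, query)), 1L)
  K <- vapply(split_terms, function(g) length(unique(g)), 1L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = keys[, 1], term_name = keys[, 2],
                    namespace = keys[, 3], k = k, K = K, n = n, N = N,
                    ratio = sprintf("%d/%d", k, K), p = p,
                    stringsAsFactors = FALSE)
  res$q <- NA_real_
  for (ns in unique(res$namespace))
    res$q[res$namespace == ns] <- fdr_adjust(res$p[res$namespace == ns])
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1).
#'
#' @param pvals p-values in (0, 1\].
#' @return q-values, same length.
#' @export
fdr_adjust <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Default stopword list for term-name summarization
#'
#' A small English function-word set; editable by passing your own set to
#' [word_frequency()].
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("of", "the", "a", "an", "to", "in", "on", "by", "via", "and", "or",
    "for", "with", "from", "into", "process", "regulation", "positive",
    "negative", "activity", "involved")
}

#' Word frequencies of significant term names
#'
#' Lowercases, tokenizes on non-alphanumeric characters, drops stopwords
#' and counts the remaining words; sorted by count (descending) then
#' alphabetically.
#'
#' @param term_names character vector of term names.
#' @param stopwords words to drop.
#' @return Data frame with columns `word`, `count` (possibly empty).
#' @export
word_frequency <- function(term_names, stopwords = default_stopwords()) {
  words <- unlist(strsplit(tolower(term_names), "[^a-z0-9]+"))
  words <- words[nzchar(words) & !(words %in% tolower(stopwords))]
  if (!length(words))
    return(data.frame(word = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(words)
  df <- data.frame(word = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$word), , drop = FALSE]
  rownames(df) <- NULL
  df
}
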