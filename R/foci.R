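#' Experiments and foci tables
#'
#' An *experiment* is a single contrast analysis from one study: a set of
#' reported peak ("focus") coordinates plus the number of subjects scanned.
#' A `foci_table` is a corpus of experiments, the unit of input to ALE
#' meta-analysis; a `coordinate_database` is a foci table with searchable
#' per-experiment labels, standing in for a large literature database.
#'
#' @param id experiment identifier (unique within a table).
#' @param study_id identifier of the publication the contrast comes from.
#' @param n_subjects number of subjects (>= 1).
#' @param foci numeric matrix (n x 3) of peak coordinates, mm.
#' @param space coordinate space of the foci.
#' @param labels named character vector of free-form labels (task,
#'   contrast, network, ...).
#' @return `experiment()` an object of class `experiment`.
#' @export
experiment <- function(id, study_id = id, n_subjects, foci,
                       space = "MNI152", labels = character()) {
  foci <- matrix(as.numeric(foci), ncol = 3)
  if (nrow(foci) < 1L) stop("experiment needs at least one focus", call. = FALSE)
  if (!all(is.finite(foci)) || any(abs(foci) > 200))
    stop("foci must be finite and within 200 mm of the origin", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be a positive integer", call. = FALSE)
  structure(list(id = as.character(id), study_id = as.character(study_id),
                 n_subjects = n_subjects, foci = foci, space = space,
                 labels = labels),
            class = "experiment")
}

#' @param experiments list of [experiment()] objects with unique ids.
#' @param name corpus name.
#' @rdname experiment
#' @export
foci_table <- function(experiments, name = "foci") {
  stopifnot(length(experiments) >= 1L)
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("experiment ids must be unique", call. = FALSE)
  structure(list(experiments = experiments, name = name),
            class = "foci_table")
}

#' @rdname experiment
#' @export
coordinate_database <- function(experiments, name = "database") {
  ft <- foci_table(experiments, name)
  class(ft) <- c("coordinate_database", "foci_table")
  ft
}

#' @export
print.foci_table <- function(x, ...) {
  cat(sprintf("<%s> '%s': %d experiments, %d foci, %d subjects\n",
              class(x)[1], x$name, n_experiments(x), n_foci(x),
              sum(vapply(x$experiments, `[[`, 1L, "n_subjects"))))
  invisible(x)
}

#' @rdname experiment
#' @param x a `foci_table`.
#' @export
n_experiments <- function(x) length(x$experiments)

#' @rdname experiment
#' @export
n_foci <- function(x) sum(vapply(x$experiments, function(e) nrow(e$foci), 1L))

#' Read and write foci tables
#'
#' Delimited text (comma or tab, auto-detected) with one row per focus and
#' columns `study_id`, `experiment_id`, `n_subjects`, `x`, `y`, `z`;
#' additional columns are kept as per-experiment labels.
#'
#' @param path file path.
#' @param space coordinate space of the stored coordinates.
#' @return A [foci_table()] grouping rows into experiments.
#' @export
read_foci_table <- function(path, space = "MNI152") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("study_id", "experiment_id", "n_subjects", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric coordinate in column '", col, "' at row ", bad[1],
           call. = FALSE)
    df[[col]] <- v
  }
  ns <- suppressWarnings(as.integer(df$n_subjects))
  bad <- which(is.na(ns) | ns < 1L)
  if (length(bad))
    stop("invalid n_subjects at row ", bad[1], " (must be >= 1)",
         call. = FALSE)
  extra <- setdiff(names(df), need)
  exps <- lapply(split(seq_len(nrow(df)), df$experiment_id), function(rows) {
    sub <- df[rows, , drop = FALSE]
    labels <- if (length(extra))
      vapply(extra, function(cc) as.character(sub[[cc]][1]), "") else
      character()
    experiment(id = sub$experiment_id[1], study_id = sub$study_id[1],
               n_subjects = ns[rows[1]],
               foci = as.matrix(sub[, c("x", "y", "z")]),
               space = space, labels = labels)
  })
  foci_table(unname(exps), name = sub("\\.[^.]+$", "", basename(path)))
}

#' @param table a [foci_table()].
#' @param sep field separator for writing.
#' @rdname read_foci_table
#' @export
write_foci_table <- function(table, path, sep = ",") {
  rows <- lapply(table$experiments, function(e) {
    data.frame(study_id = e$study_id, experiment_id = e$id,
               n_subjects = e$n_subjects,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# All foci of a set of experiments, rows stacked
all_foci <- function(table) do.call(rbind, lapply(table$experiments, `[[`, "foci"))
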