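#' MMAC-style activity table
#'
#' The carrier for one split (training or test) of one target: a molecule
#' identifier per row, one activity value per row (in the target's own
#' units, e.g. pIC50 or log D - activities are never normalized or
#' rescaled), and a matrix of non-negative descriptor counts with one named
#' column per substructure descriptor.
#'
#' @param molecule_ids character vector of molecule identifiers.
#' @param activities numeric vector, one activity per molecule.
#' @param descriptors numeric matrix (integer counts on input; may hold
#'   non-integers after [log_transform()]), entries >= 0, with unique
#'   column names.
#' @return an object of class `activity_table`.
#' @export
activity_table <- function(molecule_ids, activities, descriptors) {
  molecule_ids <- as.character(molecule_ids)
  activities <- as.numeric(activities)
  descriptors <- as.matrix(descriptors)
  if (length(molecule_ids) != length(activities) ||
      length(molecule_ids) != nrow(descriptors)) {
    stop("molecule_ids, activities and descriptor rows must agree in length")
  }
  if (anyNA(activities)) {
    stop("activities contain missing values (rows ",
         paste(which(is.na(activities)), collapse = ", "), ")")
  }
  if (is.null(colnames(descriptors)) && ncol(descriptors) > 0L) {
    stop("descriptor columns must be named")
  }
  if (anyDuplicated(colnames(descriptors))) {
    stop("duplicate descriptor column names: ",
         paste(unique(colnames(descriptors)[duplicated(colnames(descriptors))]),
               collapse = ", "))
  }
  if (anyNA(descriptors)) stop("descriptor entries must not be missing")
  if (any(descriptors < 0)) stop("descriptor entries must be >= 0")
  structure(
    list(molecule_ids = molecule_ids,
         activities = activities,
         descriptors = descriptors),
    class = "activity_table"
  )
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("<activity_table: %d molecules x %d descriptors>\n",
              length(x$molecule_ids), ncol(x$descriptors)))
  invisible(x)
}

#' Number of molecules in an activity table
#' @param table an [activity_table()].
#' @export
n_molecules <- function(table) length(table$molecule_ids)

#' Read an MMAC-format activity CSV
#'
#' The expected layout is the competition file convention: a molecule-id
#' column, an activity column, then one column per descriptor holding
#' non-negative integer counts. Gzip-compressed files are read
#' transparently. Missing descriptor cells become 0; a missing or
#' non-numeric activity is an error naming the offending row.
#'
#' @param path CSV (or .csv.gz) file path.
#' @param id_col name of the molecule-id column (default `"MOLECULE"`).
#' @param act_col name of the activity column (default `"Act"`).
#' @return an [activity_table()].
#' @export
read_activity_table <- function(path, id_col = "MOLECULE", act_col = "Act") {
  # parse the header with full CSV quoting rules (descriptor keys contain
  # commas); fread silently renames duplicates, so check the raw fields
  raw_header <- as.character(utils::read.csv(path, nrows = 1L, header = FALSE,
                                             colClasses = "character")[1L, ])
  header <- raw_header
  if (anyDuplicated(raw_header)) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(raw_header[duplicated(raw_header)]), collapse = ", "))
  }
  if (!id_col %in% header) stop("missing molecule-id column '", id_col, "'")
  if (!act_col %in% header) stop("missing activity column '", act_col, "'")

  dt <- if (grepl("\\.gz$", path)) {
    # route gz through a base connection (transparent decompression)
    data.table::fread(text = readLines(path), header = TRUE,
                      check.names = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, header = TRUE, check.names = FALSE,
                      showProgress = FALSE)
  }
  ids <- as.character(dt[[id_col]])
  act_raw <- dt[[act_col]]
  act <- suppressWarnings(as.numeric(act_raw))
  bad <- which(is.na(act))
  if (length(bad) > 0L) {
    stop("non-numeric or missing activity in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " of ", path)
  }
  desc_cols <- setdiff(header, c(id_col, act_col))
  desc <- as.matrix(dt[, desc_cols, with = FALSE])
  storage.mode(desc) <- "numeric"
  desc[is.na(desc)] <- 0
  if (any(desc < 0)) {
    stop("negative descriptor count in ", path)
  }
  activity_table(ids, act, desc)
}

#' Write an activity table as an MMAC-format CSV
#'
#' @param table an [activity_table()].
#' @param path output file; a `.gz` suffix triggers compression.
#' @inheritParams read_activity_table
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path, id_col = "MOLECULE", act_col = "Act") {
  stopifnot(inherits(table, "activity_table"))
  dt <- data.table::data.table(table$molecule_ids, table$activities)
  data.table::setnames(dt, c(id_col, act_col))
  if (ncol(table$descriptors) > 0L) {
    dt <- cbind(dt, data.table::as.data.table(table$descriptors))
  }
  data.table::fwrite(dt, path, compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Unify the descriptor vocabularies of a train and a test table
#'
#' Competition files omit descriptor columns that are all-zero within a
#' split, so the train and test fingerprint vectors of one target differ in
#' size. Alignment restores the missing substructures by adding all-zero
#' columns, giving both splits the identical ordered vocabulary (the sorted
#' union of the two column-name sets). Counts of shared columns are
#' preserved exactly; the unified width is what allows test-set evaluation
#' after every training epoch.
#'
#' @param train,test [activity_table()] objects.
#' @return an object of class `aligned_dataset`: list with `train`, `test`
#'   (re-columned tables) and `vocabulary` (ordered descriptor names).
#' @export
align_vocabularies <- function(train, test) {
  stopifnot(inherits(train, "activity_table"), inherits(test, "activity_table"))
  vocab <- sort(union(colnames(train$descriptors), colnames(test$descriptors)))
  expand <- function(tab) {
    m <- matrix(0, nrow = n_molecules(tab), ncol = length(vocab),
                dimnames = list(NULL, vocab))
    present <- intersect(colnames(tab$descriptors), vocab)
    m[, present] <- tab$descriptors[, present, drop = FALSE]
    activity_table(tab$molecule_ids, tab$activities, m)
  }
  structure(
    list(train = expand(train), test = expand(test), vocabulary = vocab),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset: %d train / %d test molecules, %d merged descriptors>\n",
              n_molecules(x$train), n_molecules(x$test), length(x$vocabulary)))
  invisible(x)
}

#' Logarithmic transform of descriptor counts
#'
#' Replaces every descriptor entry x by log(1 + x), leaving activities
#' untouched. log(1+x) rather than log(x) because count fingerprints are
#' mostly zeros, and log(1+0) = 0 keeps the sparsity pattern. This is the
#' "Log Transform" preprocessing of the LOG settings in the benchmark grid.
#'
#' @param table an [activity_table()] with non-negative descriptor entries.
#' @return a new `activity_table` with transformed descriptors.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  if (any(table$descriptors < 0)) stop("descriptor entries must be >= 0")
  activity_table(table$molecule_ids, table$activities, log1p(table$descriptors))
}
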