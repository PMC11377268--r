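#' Read a gaitpdb-dialect recording
#'
#' Parses one whitespace-delimited text recording in the force-platform
#' dialect: 19 numeric columns per row (timestamp in seconds, 8 sensors per
#' foot, 2 per-foot sums), 100 frames/s. The source id is the file name
#' stem.
#'
#' @param path Path to the text file.
#' @return A [raw_recording()] with `dialect = "gaitpdb-19col"`.
#' @export
read_gaitpdb <- function(path) {
  nf <- count.fields(path)
  bad <- which(nf != 19)
  if (length(bad))
    abort(sprintf("line %d of %s has %d columns; expected 19",
                  bad[1], path, nf[bad[1]]))
  values <- tryCatch(
    as.matrix(read.table(path, colClasses = "numeric")),
    error = function(e)
      abort(paste0("non-numeric token in ", path, ": ", conditionMessage(e))))
  raw_recording(values, dialect = "gaitpdb-19col", sample_rate = 100,
                source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a recording in the gaitpdb text dialect
#'
#' Emits whitespace-delimited numeric text, one row per frame, 19 columns,
#' the timestamp at 0.01 s steps -- the exact format [read_gaitpdb()]
#' parses, so generated fixtures round-trip through the reader.
#'
#' @param raw A [raw_recording()] with `dialect = "gaitpdb-19col"` and its
#'   timestamp column present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaitpdb <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"),
            raw$dialect == "gaitpdb-19col", raw$has_timestamp)
  write.table(format(raw$values, digits = 17, scientific = FALSE,
                     trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject demographics table
#'
#' Tab-delimited table with at least columns `ID` (record/subject
#' identifier), `Group` (`PD` or `CO`) and `HoehnYahr` (severity stage;
#' empty or 0 for controls). Used to label gaitpdb recordings.
#'
#' @param path Path to the tab-delimited file.
#' @return Tibble with columns `id`, `group`, `hoehn_yahr`.
#' @export
read_demographics <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID", "Group", "HoehnYahr")
  if (!all(need %in% names(df)))
    abort(paste0("demographics table must have columns: ",
                 paste(need, collapse = ", ")))
  tibble::tibble(id = as.character(df$ID),
                 group = as.character(df$Group),
                 hoehn_yahr = suppressWarnings(as.numeric(df$HoehnYahr)))
}

#' Assemble a labelled dataset from raw gaitpdb recordings
#'
#' Reads every matching recording in a directory, drops timestamps, chunks
#' into fixed windows and attaches severity labels from a demographics
#' table. Subjects whose stage is not one of 0/2/2.5/3 are dropped.
#'
#' @param raw_dir Directory of gaitpdb text recordings.
#' @param demographics Path to the demographics table
#'   ([read_demographics()]).
#' @param window_len Frames per window.
#' @param pattern Filename glob-style regular expression filter (record-type
#'   filter; e.g. `"_01\\\\.txt$"` for first walks only).
#' @param dataset_tag Tag stored on the dataset.
#' @return A [gait_dataset()] of `window_len` x 18 windows.
#' @export
read_gaitpdb_dataset <- function(raw_dir, demographics, window_len = 500,
                                 pattern = "\\.txt$", dataset_tag = "gaitpdb") {
  demo <- read_demographics(demographics)
  files <- list.files(raw_dir, pattern = pattern, full.names = TRUE)
  files <- setdiff(normalizePath(files),
                   normalizePath(demographics, mustWork = FALSE))
  if (!length(files)) abort(paste0("no recordings match in ", raw_dir))
  wins <- list(); labels <- character(); subs <- character(); widx <- integer()
  for (f in files) {
    rec <- drop_timestamp(read_gaitpdb(f))
    subject <- sub("_.*$", "", rec$source_id)
    row <- demo[demo$id == subject, ]
    if (!nrow(row)) next
    stage <- if (identical(row$group[1], "CO") || is.na(row$hoehn_yahr[1]))
      0 else row$hoehn_yahr[1]
    if (!stage %in% c(0, 2, 2.5, 3)) next
    for (w in chunk(rec, window_len)) {
      wins[[length(wins) + 1]] <- w$values
      labels <- c(labels, format(stage, drop0trailing = TRUE))
      subs <- c(subs, subject)
      widx <- c(widx, w$window_index)
    }
  }
  if (!length(wins)) abort("no labelled windows produced")
  values <- array(0, c(length(wins), window_len, 18))
  for (i in seq_along(wins)) values[i, , ] <- wins[[i]]
  gait_dataset(values, factor(labels, levels = c("0", "2", "2.5", "3")),
               subs, classes = c("0", "2", "2.5", "3"), window_index = widx,
               dataset_tag = dataset_tag, sample_rate = 100)
}

#' Save / load package objects
#'
#' Datasets, trained models and relevance maps are plain R lists; they are
#' serialized with RDS. A JSON sidecar with the generator configuration is
#' written next to datasets for provenance.
#'
#' @param x Object to save.
#' @param path Destination `.rds` path.
#' @return `path` (save) or the restored object (load), invisibly for save.
#' @export
save_gait_object <- function(x, path) {
  saveRDS(x, path)
  if (inherits(x, "gait_dataset") && !is.null(x$config)) {
    side <- sub("\\.rds$", ".json", path)
    cfg <- x$config; class(cfg) <- NULL
    jsonlite::write_json(cfg, side, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_gait_object
#' @export
load_gait_object <- function(path) readRDS(path)
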