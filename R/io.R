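table_schemas <- list(
  labeling = c("population", "time_h", "fraction_labeled", "sd", "n_animals"),
  sections = c("replicate", "section", "ap_position_um", "n_pcna",
               "n_mitotic", "section_thickness_um"),
  geometry = c("replicate", "mean_cell_length_um"),
  spindle = c("cell_id", "group", "day", "ax", "ay", "az", "bx", "by", "bz",
              "cx", "cy", "cz", "dx", "dy", "dz", "ap_position_um"),
  cleavage = c("cell_id", "group", "sx1", "sy1", "sx2", "sy2",
               "apx1", "apy1", "apx2", "apy2"),
  mitotic_labeling = c("time_h", "fraction_labeled")
)

#' Read a validated delimited table
#'
#' Reads a tab-separated (or comma-separated) table and validates it
#' against one of the package's named input schemas. Missing required
#' columns raise an error naming the column; non-numeric values in numeric
#' columns raise an error naming row and column; unknown extra columns are
#' accepted with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"labeling"`, `"sections"`, `"geometry"`,
#'   `"spindle"`, `"cleavage"`, `"mitotic_labeling"`.
#' @param sep Field separator (default tab).
#' @return Validated data frame.
#' @export
read_table <- function(path, schema, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- match.arg(schema, names(table_schemas))
  need <- table_schemas[[schema]]
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema '", schema, "': missing column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  char_cols <- c("population", "group", "cell_id")
  for (col in setdiff(need, char_cols)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1])
      df[[col]] <- vn
    }
  }
  df
}

#' Read an nCounter count matrix from a delimited file
#'
#' Expects a header row; first column probe id, second column probe class
#' (`endogenous`/`positive`/`negative`/`housekeeping`), remaining columns
#' one per sample.
#'
#' @param path File path.
#' @param sample_group Group label per sample column (defaults to the
#'   column names).
#' @param sep Field separator (default tab).
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, sample_group = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4L) stop("count matrix needs probe, class and >= 2 samples")
  cts <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(cts)) stop("sample columns must be numeric")
  rownames(cts) <- df[[1]]
  if (is.null(sample_group)) sample_group <- colnames(cts)
  count_matrix(cts, df[[2]], sample_group)
}

#' Read nCounter RCC files from a directory
#'
#' Minimal reader for the sectioned RCC dialect: only the
#' `<Code_Summary>` block (CSV lines `CodeClass,Name,Accession,Count`) is
#' parsed; one RCC file per sample. Code classes are mapped to the
#' package's probe classes (`Positive` -> positive, `Negative` ->
#' negative, `Housekeeping` -> housekeeping, anything else endogenous).
#'
#' @param dir Directory containing `.RCC` files.
#' @param sample_group Optional group label per file (alphabetical order).
#' @return A [count_matrix].
#' @export
read_rcc_dir <- function(dir, sample_group = NULL) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no RCC files in ", dir)
  one <- function(f) {
    lines <- readLines(f, warn = FALSE)
    i0 <- grep("^<Code_Summary>", lines)
    i1 <- grep("^</Code_Summary>", lines)
    if (length(i0) != 1L || length(i1) != 1L || i1 <= i0)
      stop("no <Code_Summary> block in ", f)
    block <- lines[(i0 + 1):(i1 - 1)]
    df <- utils::read.csv(text = paste(block, collapse = "\n"),
                          stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    df[c("codeclass", "name", "count")]
  }
  tabs <- lapply(files, one)
  probes <- tabs[[1]]$name
  for (tb in tabs[-1])
    if (!identical(tb$name, probes))
      stop("RCC files disagree on probe set")
  cts <- vapply(tabs, function(tb) as.numeric(tb$count),
                numeric(length(probes)))
  cts <- matrix(cts, nrow = length(probes),
                dimnames = list(probes, sub("\\.rcc$", "",
                                            basename(files),
                                            ignore.case = TRUE)))
  cls <- tolower(tabs[[1]]$codeclass)
  probe_class <- ifelse(cls == "positive", "positive",
                 ifelse(cls == "negative", "negative",
                 ifelse(cls == "housekeeping", "housekeeping", "endogenous")))
  if (is.null(sample_group)) sample_group <- colnames(cts)
  count_matrix(cts, probe_class, sample_group)
}

#' Write an analysis result to disk
#'
#' JSON output (full double precision, scalars unboxed) or TSV for tabular
#' results. Refuses to overwrite an existing file unless `force = TRUE`.
#'
#' @param result A list or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (TSV requires a data frame).
#' @param force Overwrite an existing file.
#' @return The path, invisibly.
#' @export
write_results <- function(result, path, format = c("json", "tsv"),
                          force = FALSE) {
  format <- match.arg(format)
  if (file.exists(path) && !force)
    stop("output file exists (use force = TRUE to overwrite): ", path)
  if (format == "json") {
    stripped <- unclass_deep(result)
    jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(result)) stop("TSV output requires a data frame")
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}

#' Evaluate the labeling model on a time grid
#'
#' Convenience export of the fitted curve for plotting or downstream use.
#'
#' @param fit A `cell_cycle_fit`.
#' @param times Time grid in hours.
#' @return Data frame with `time_h`, `fraction_labeled`,
#'   `growth_fraction`, `rprime`.
#' @export
model_curve <- function(fit, times = seq(0, 240, by = 2)) {
  stopifnot(inherits(fit, "cell_cycle_fit"))
  data.frame(time_h = times,
             fraction_labeled = labeled_fraction(times, fit$params),
             growth_fraction = growth_fraction(times, fit$params),
             rprime = rprime(times, fit$params))
}
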