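#' Read sensorgram cycles from delimited text
#'
#' Accepts comma- or tab-delimited files with a mandatory header.
#' Required columns: `time_s`, `response_RU`; metadata columns `conc_M`
#' and `assoc_end_s` (constant within a cycle). Long format with a
#' `cycle` column holds several cycles per file; without it the file is
#' one cycle.
#'
#' @param path file path.
#' @return List of `sensorgram` objects.
#' @export
read_sensorgram_table <- function(path) {
  tab <- .read_delim(path)
  req <- c("time_s", "response_RU", "conc_M", "assoc_end_s")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cycle" %in% names(tab)) tab$cycle <- 1
  lapply(split(tab, tab$cycle), function(d) {
    d <- d[order(d$time_s), ]
    sensorgram(d$time_s, d$response_RU,
               analyte_concentration = d$conc_M[1],
               association_end = d$assoc_end_s[1])
  })
}

#' Write sensorgram cycles as delimited text
#'
#' @param sensorgrams list of `sensorgram` objects.
#' @param path output file; extension `.csv` writes comma-delimited,
#'   anything else tab-delimited.
#' @return `path`, invisibly.
#' @export
write_sensorgram_table <- function(sensorgrams, path) {
  tab <- do.call(rbind, lapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    data.frame(cycle = i, time_s = sg$time, response_RU = sg$signal,
               conc_M = attr(sg, "analyte_concentration"),
               assoc_end_s = attr(sg, "association_end"))
  }))
  .write_delim(tab, path)
}

#' Read exchange time courses from delimited text
#'
#' Required columns: `time_s`, `fluorescence`; optional metadata columns
#' `conc_M` (substrate), `enzyme_M`, `phase`, and `well` for several time
#' courses per file.
#'
#' @param path file path.
#' @return List of `exchange_timecourse` objects.
#' @export
read_exchange_table <- function(path) {
  tab <- .read_delim(path)
  miss <- setdiff(c("time_s", "fluorescence"), names(tab))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"well" %in% names(tab)) tab$well <- 1
  lapply(split(tab, tab$well), function(d) {
    d <- d[order(d$time_s), ]
    exchange_timecourse(
      d$time_s, d$fluorescence,
      substrate_concentration = if ("conc_M" %in% names(d)) d$conc_M[1]
        else NA_real_,
      enzyme_concentration = if ("enzyme_M" %in% names(d)) d$enzyme_M[1]
        else NA_real_,
      phase = if ("phase" %in% names(d)) d$phase[1] else "loading")
  })
}

#' Read a FRET titration from delimited text
#'
#' Required columns: `conc_M`, `fret_ratio`; optional `replicate`
#' (technical replicates are averaged per concentration).
#'
#' @param path file path.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path) {
  tab <- .read_delim(path)
  miss <- setdiff(c("conc_M", "fret_ratio"), names(tab))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(fret_ratio ~ conc_M, data = tab, FUN = mean)
  titration_series(agg$conc_M, agg$fret_ratio)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_delim <- function(tab, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a flat key-value parameter table
#'
#' @param values named list or vector of fitted parameters.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(values, path) {
  tab <- data.frame(parameter = names(values),
                    value = vapply(values, function(v)
                      format(v, digits = 15), character(1)))
  .write_delim(tab, path)
}
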