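# Corpus input/output: JSONL (one encounter per line, notes embedded) or a
# pair of CSVs (encounters, notes) joined on encounter_id; truth and result
# tables as CSV.

encounter_to_list <- function(enc) {
  list(
    encounter_id = enc$encounter_id,
    patient_id = enc$patient_id,
    visit_date = format(enc$visit_date),
    diagnosis_codes = enc$diagnosis_codes,
    notes = enc$notes
  )
}

list_to_encounter <- function(x) {
  codes <- x$diagnosis_codes
  if (is.null(codes) || !NROW(codes)) codes <- NULL
  notes <- x$notes
  if (is.null(notes) || !NROW(notes)) notes <- NULL
  encounter(x$encounter_id, x$patient_id, x$visit_date,
            diagnosis_codes = codes, notes = notes)
}

#' Write encounters as JSONL
#'
#' One JSON object per line; `diagnosis_codes` and `notes` are arrays of
#' objects. The format round-trips losslessly through
#' [read_encounters_jsonl()].
#'
#' @param encounters list of [encounter()] objects.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_encounters_jsonl <- function(encounters, path) {
  lines <- vapply(encounters, function(enc) {
    jsonlite::toJSON(encounter_to_list(enc), auto_unbox = TRUE,
                     dataframe = "rows", na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read encounters from JSONL
#'
#' @param path file written by [write_encounters_jsonl()] (or conforming).
#' @return list of [encounter()] objects.
#' @export
read_encounters_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    list_to_encounter(jsonlite::fromJSON(l, simplifyDataFrame = TRUE))
  })
}

#' Write encounters as a CSV pair
#'
#' `encounters_path` gets one row per encounter (`encounter_id`,
#' `patient_id`, `visit_date`, `diagnosis_codes` as a `;`-separated list of
#' `revision:code`); `notes_path` gets one row per note, joined on
#' `encounter_id`.
#'
#' @param encounters list of [encounter()] objects.
#' @param encounters_path,notes_path destination files.
#' @return invisibly, the two paths.
#' @export
write_encounters_csv <- function(encounters, encounters_path, notes_path) {
  enc_tab <- do.call(rbind, lapply(encounters, function(e) {
    codes <- e$diagnosis_codes
    data.frame(
      encounter_id = e$encounter_id, patient_id = e$patient_id,
      visit_date = format(e$visit_date),
      diagnosis_codes = paste(paste0(codes$revision, ":", codes$code),
                              collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  note_tab <- do.call(rbind, lapply(encounters, function(e) {
    if (!nrow(e$notes)) return(NULL)
    cbind(data.frame(encounter_id = e$encounter_id,
                     stringsAsFactors = FALSE), e$notes)
  }))
  if (is.null(note_tab)) {
    note_tab <- data.frame(encounter_id = character(), note_id = character(),
                           author_role = character(), text = character(),
                           stringsAsFactors = FALSE)
  }
  write.csv(enc_tab, encounters_path, row.names = FALSE)
  write.csv(note_tab, notes_path, row.names = FALSE)
  invisible(c(encounters_path, notes_path))
}

#' Read encounters from a CSV pair
#'
#' @param encounters_path,notes_path files written by
#'   [write_encounters_csv()] (or conforming).
#' @return list of [encounter()] objects.
#' @export
read_encounters_csv <- function(encounters_path, notes_path) {
  for (p in c(encounters_path, notes_path)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  enc_tab <- read.csv(encounters_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  note_tab <- read.csv(notes_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  lapply(seq_len(nrow(enc_tab)), function(i) {
    row <- enc_tab[i, ]
    codes <- NULL
    if (nzchar(row$diagnosis_codes)) {
      parts <- strsplit(row$diagnosis_codes, ";", fixed = TRUE)[[1]]
      rev_code <- strsplit(parts, ":", fixed = TRUE)
      codes <- data.frame(
        code = vapply(rev_code, `[`, "", 2L),
        revision = vapply(rev_code, `[`, "", 1L),
        stringsAsFactors = FALSE
      )
    }
    notes <- note_tab[note_tab$encounter_id == row$encounter_id,
                      c("note_id", "author_role", "text")]
    encounter(row$encounter_id, row$patient_id, row$visit_date,
              diagnosis_codes = codes,
              notes = if (nrow(notes)) notes else NULL)
  })
}

#' Write / read generator truth records
#'
#' @param truth data frame with columns `encounter_id`, `is_ipv`,
#'   `phenomena`, `phrase`.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$is_ipv <- as.logical(tab$is_ipv)
  tab
}

#' Write classification results as CSV
#'
#' @param results the `results` data frame of [classify_corpus()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$label <- as.logical(tab$label)
  tab
}
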