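# McGurk susceptibility scoring from trial-level syllable reports.

#' The canonical 29-value SOA grid (ms)
#'
#' Stimulus onset asynchronies between the visual and auditory streams:
#' 0 and +/- {33, 67, ..., 467} ms (positive = visual leading).
#'
#' @export
soa_grid <- function() {
  half <- c(33, 67, 100, 133, 167, 200, 233, 267, 300, 333, 367, 400, 433,
            467)
  sort(c(-half, 0, half))
}

valid_responses <- c("pa", "ka", "ta")

check_trials <- function(table) {
  need <- c("subject_id", "soa_ms", "trial", "response")
  if (!all(need %in% colnames(table)))
    stop("behavioral table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!table$response %in% valid_responses)
  if (length(bad))
    stop(sprintf("invalid response %s at row %d (forced choice: pa/ka/ta)",
                 table$response[bad[1]], bad[1]), call. = FALSE)
  off <- which(!table$soa_ms %in% soa_grid())
  if (length(off))
    stop(sprintf("SOA %d ms at row %d is not on the 29-value grid",
                 table$soa_ms[off[1]], off[1]), call. = FALSE)
  invisible(table)
}

#' Per-SOA response proportions for one subject
#'
#' @param table behavioral trial table with columns `subject_id`, `soa_ms`,
#'   `trial`, `response` (responses restricted to pa/ka/ta).
#' @param subject_id subject to summarize.
#' @return Data frame with one row per SOA on the grid present for the
#'   subject: columns `soa_ms`, `n`, `pa`, `ka`, `ta` (proportions summing
#'   to 1 per row).
#' @export
response_curve <- function(table, subject_id) {
  check_trials(table)
  tb <- table[table$subject_id == subject_id, ]
  if (nrow(tb) == 0) stop("unknown subject: ", subject_id, call. = FALSE)
  soas <- sort(unique(tb$soa_ms))
  out <- do.call(rbind, lapply(soas, function(s) {
    resp <- tb$response[tb$soa_ms == s]
    n <- length(resp)
    data.frame(soa_ms = s, n = n,
               pa = mean(resp == "pa"), ka = mean(resp == "ka"),
               ta = mean(resp == "ta"))
  }))
  rownames(out) <- NULL
  out
}

#' Individual McGurk susceptibility
#'
#' Proportion of illusory /ta/ reports at the SOA where the group fusion
#' curve peaks (+133 ms, visual leading).
#'
#' @inheritParams response_curve
#' @param target_soa_ms scoring SOA (default +133).
#' @return Proportion in [0, 1].
#' @export
susceptibility <- function(table, subject_id, target_soa_ms = 133) {
  check_trials(table)
  tb <- table[table$subject_id == subject_id &
                table$soa_ms == target_soa_ms, ]
  if (nrow(tb) == 0)
    stop(sprintf("no trials at SOA %d ms for subject %s", target_soa_ms,
                 subject_id), call. = FALSE)
  mean(tb$response == "ta")
}

#' Classify strong and weak McGurk perceivers
#'
#' Susceptibility above the upper band edge is "strong", below the lower
#' edge "weak", inside the closed band "excluded" (the medial-perceiver
#' exclusion; by default the band collapses to the single point 0.5, so
#' only exact 50% scores are excluded).
#'
#' @param records data frame with columns `subject_id`, `susceptibility`.
#' @param exclusion_band numeric length-2 closed interval excluded as
#'   "medial" perceivers.
#' @return The input with a `group` column (strong/weak/excluded).
#' @export
classify_perceivers <- function(records, exclusion_band = c(0.5, 0.5)) {
  stopifnot(all(records$susceptibility >= 0),
            all(records$susceptibility <= 1),
            length(exclusion_band) == 2,
            exclusion_band[1] <= exclusion_band[2])
  s <- records$susceptibility
  records$group <- ifelse(s > exclusion_band[2], "strong",
                          ifelse(s < exclusion_band[1], "weak", "excluded"))
  records
}

#' Write / read behavioral trial tables (CSV)
#'
#' Columns: `subject_id`, `soa_ms`, `trial`, `response`.
#'
#' @param table trial table.
#' @param path CSV path.
#' @export
write_trials <- function(table, path) {
  check_trials(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  check_trials(tb)
  tb
}
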