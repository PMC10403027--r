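#' Build daily state sequences from care episodes
#'
#' Expands closed day-offset intervals of care episodes into per-day state
#' sequences over the observation window. Day offsets count days before
#' death: offset 0 is the day of death, offset `days - 1` is the first day
#' of the window. Sequence position t is therefore `days - offset`, so the
#' last column is the day of death. Days covered by no episode are `HOME`.
#' When episodes overlap on a day, the state with the highest care
#' intensity wins, in the fixed priority order
#' `ACUTE > REHAB > HAH > PSY > HOME`.
#'
#' @param episodes a data.frame with columns `patient_id`, `state` (label or
#'   single-character code), `start_days_before_death` and
#'   `end_days_before_death` (integers, start >= end, both in
#'   `[0, days - 1]`; the interval is closed).
#' @param ids patient ids to encode; defaults to the ids present in
#'   `episodes`. Ids with no episodes yield all-`HOME` sequences.
#' @param days window length in days (default 365).
#' @return a [CareSequences-class] object with one row per id.
#' @examples
#' ep <- data.frame(patient_id = "p1", state = "ACUTE",
#'                  start_days_before_death = 9, end_days_before_death = 0)
#' cs <- encodeDailyStates(ep)
#' table(seqStates(cs, "label"))
#' @export
encodeDailyStates <- function(episodes, ids = NULL, days = 365L) {
  days <- as.integer(days)
  req <- c("patient_id", "state", "start_days_before_death",
           "end_days_before_death")
  if (!all(req %in% names(episodes)))
    stop("episodes must have columns: ", paste(req, collapse = ", "))
  if (is.null(ids)) ids <- unique(as.character(episodes$patient_id))
  ids <- as.character(ids)
  n <- length(ids)
  m <- matrix(.HOME, nrow = n, ncol = days)
  if (nrow(episodes)) {
    st <- .stateToInt(episodes$state)
    a <- as.integer(episodes$start_days_before_death)
    b <- as.integer(episodes$end_days_before_death)
    if (any(a < b)) stop("start_days_before_death must be >= end_days_before_death")
    if (any(b < 0L) || any(a > days - 1L))
      stop("episode day offsets must lie in [0, ", days - 1L, "]")
    row <- match(as.character(episodes$patient_id), ids)
    if (anyNA(row)) stop("episode for patient not in 'ids'")
    # apply lowest-priority states first so higher priority overwrites
    for (e in order(st, decreasing = TRUE)) {
      cols <- (days - a[e]):(days - b[e])
      cur <- m[row[e], cols]
      m[row[e], cols] <- pmin(cur, st[e])
    }
  }
  new("CareSequences", ids = ids, states = m)
}

#' Read and write care-state sequence tables
#'
#' Two plain-text serializations are supported. `wide`: one row per patient
#' with the packed sequence as a string of single-character state codes (one
#' character per day, see [careStateCodes()]). `rle`: the run-length-encoded
#' form `code:length;code:length;...`. With `format = "parquet"` the wide
#' table is written as a columnar binary file (requires the arrow package).
#'
#' @param x a [CareSequences-class] object.
#' @param file path to write to / read from.
#' @param layout `"wide"` or `"rle"`.
#' @param format `"csv"` (delimited text) or `"parquet"`.
#' @return `writeSequences()` returns `file` invisibly; `readSequences()`
#'   returns a [CareSequences-class] object.
#' @export
writeSequences <- function(x, file, layout = c("wide", "rle"),
                           format = c("csv", "parquet")) {
  layout <- match.arg(layout)
  format <- match.arg(format)
  codes <- unname(careStateCodes())
  if (layout == "wide") {
    packed <- apply(seqStates(x, "code"), 1L, paste0, collapse = "")
    df <- data.frame(patient_id = seqIds(x), states = unname(packed),
                     stringsAsFactors = FALSE)
  } else {
    rlestr <- apply(x@states, 1L, function(r) {
      e <- rle(r)
      paste0(codes[e$values], ":", e$lengths, collapse = ";")
    })
    df <- data.frame(patient_id = seqIds(x), states_rle = unname(rlestr),
                     stringsAsFactors = FALSE)
  }
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet output")
    arrow::write_parquet(df, file)
  } else {
    data.table::fwrite(df, file)
  }
  invisible(file)
}

#' @rdname writeSequences
#' @export
readSequences <- function(file, format = c("csv", "parquet")) {
  format <- match.arg(format)
  df <- if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet input")
    as.data.frame(arrow::read_parquet(file))
  } else {
    as.data.frame(data.table::fread(file, colClasses = "character"))
  }
  if ("states" %in% names(df)) {
    CareSequences(df$states, ids = df$patient_id)
  } else if ("states_rle" %in% names(df)) {
    rows <- lapply(strsplit(df$states_rle, ";", fixed = TRUE), function(runs) {
      parts <- strsplit(runs, ":", fixed = TRUE)
      unlist(lapply(parts, function(p) rep(p[1], as.integer(p[2]))),
             use.names = FALSE)
    })
    L <- lengths(rows)
    if (length(unique(L)) > 1L)
      stop("run-length-encoded sequences decode to unequal lengths")
    CareSequences(matrix(.stateToInt(unlist(rows, use.names = FALSE)),
                         nrow = nrow(df), byrow = TRUE),
                  ids = df$patient_id)
  } else {
    stop("file has neither a 'states' nor a 'states_rle' column")
  }
}
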