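#' Construct a weekly symptom panel
#'
#' @param scores named list of T x n numeric matrices (names among `dep`,
#'   `ins`, `hypo`; identical dimensions; `NA` = missing week). Column names
#'   are participant ids.
#' @param covariates data.frame with one row per participant and the binary
#'   columns `bd2`, `female`, `age55`, `rapid`.
#' @return a [MoodPanel-class].
#' @export
MoodPanel <- function(scores, covariates) {
  stopifnot(is.list(scores), length(scores) > 0)
  T <- nrow(scores[[1]])
  n <- ncol(scores[[1]])
  ids <- colnames(scores[[1]])
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  scores <- lapply(scores, function(m) {
    stopifnot(identical(dim(m), c(T, n)))
    dimnames(m) <- list(NULL, ids)
    m
  })
  cd <- S4Vectors::DataFrame(covariates[, COVARIATE_NAMES, drop = FALSE],
                             row.names = ids)
  for (v in COVARIATE_NAMES) cd[[v]] <- as.integer(cd[[v]])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = scores, colData = cd,
    rowData = S4Vectors::DataFrame(week = seq_len(T)))
  methods::new("MoodPanel", se)
}

#' @describeIn MoodPanel baseline covariates, one row per participant.
#' @param panel a `MoodPanel`.
#' @export
covariates <- function(panel) {
  as.data.frame(SummarizedExperiment::colData(panel))[, COVARIATE_NAMES,
                                                      drop = FALSE]
}

#' @describeIn MoodPanel participant identifiers.
#' @export
participantIds <- function(panel) colnames(panel)

#' @describeIn MoodPanel the T x n score matrix of one process.
#' @param process one of `"dep"`, `"ins"`, `"hypo"`.
#' @export
scoreMatrix <- function(panel, process) {
  SummarizedExperiment::assay(panel, process)
}

#' @describeIn MoodPanel names of the scored processes present.
#' @export
processNames <- function(panel) SummarizedExperiment::assayNames(panel)

setMethod("show", "MoodPanel", function(object) {
  cat(sprintf("MoodPanel: %d participants x %d weeks; outcomes: %s\n",
              ncol(object), nrow(object),
              paste(processNames(object), collapse = ", ")))
  cat(sprintf("overall missing fraction: %.3f\n",
              mean(is.na(SummarizedExperiment::assay(object, 1)))))
})

#' Read a weekly panel from CSV
#'
#' Long format, one row per participant-week, header required. Columns: `id`,
#' `week`, the binary covariates `bd2`, `female`, `age55`, `rapid`, then
#' either pre-computed scores `dep`, `ins`, `hypo` (empty cell = missing;
#' `dialect = "scores"`) or raw items `qids_01..qids_16`, `asrm_01..asrm_05`
#' (`dialect = "items"`), which are scored on read. Weeks absent from the file
#' become explicit missing cells on the common 1..T grid.
#'
#' @param path CSV file path.
#' @param dialect `"scores"` or `"items"`.
#' @param nWeeks grid length T; defaults to the largest week present.
#' @return a [MoodPanel-class].
#' @export
readPanel <- function(path, dialect = c("scores", "items"), nWeeks = NULL) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "week", COVARIATE_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$week != as.integer(df$week)) || any(is.na(df$week)))
    stop("non-integer week index")
  df$week <- as.integer(df$week)
  if (any(df$week < 1L)) stop("week indices must be >= 1")
  if (anyDuplicated(df[, c("id", "week")]))
    stop("duplicate (id, week) rows")
  for (v in COVARIATE_NAMES) {
    if (!all(df[[v]] %in% c(0, 1)))
      stop(sprintf("covariate '%s' outside {0,1}", v))
    if (any(tapply(df[[v]], df$id, function(x) length(unique(x))) > 1))
      stop(sprintf("covariate '%s' varies within a participant", v))
  }
  if (dialect == "items") {
    qcols <- sprintf("qids_%02d", 1:16)
    acols <- sprintf("asrm_%02d", 1:5)
    miss <- setdiff(c(qcols, acols), names(df))
    if (length(miss))
      stop("items dialect requires columns: ", paste(miss, collapse = ", "))
    df$dep <- scoreQidsDepression(df[, qcols])
    df$ins <- scoreQidsInsomnia(df[, qcols])
    df$hypo <- scoreAsrm(df[, acols])
  }
  present <- intersect(names(PROCESS_BOUNDS), names(df))
  if (length(present) == 0)
    stop("no outcome columns (dep, ins, hypo) found")
  ids <- unique(df$id)
  T <- if (is.null(nWeeks)) max(df$week) else as.integer(nWeeks)
  if (any(df$week > T)) stop("week index exceeds the grid length")
  ridx <- df$week + T * (match(df$id, ids) - 1L)
  scores <- lapply(setNames(present, present), function(v) {
    m <- matrix(NA_real_, T, length(ids), dimnames = list(NULL, ids))
    m[ridx] <- as.numeric(df[[v]])
    m
  })
  cov <- df[match(ids, df$id), COVARIATE_NAMES, drop = FALSE]
  MoodPanel(scores, cov)
}

#' Write a weekly panel to CSV (scores dialect)
#'
#' Inverse of [readPanel()]: emits one row per participant-week on the full
#' grid with empty cells for missing scores, so that a read/write round trip
#' preserves every value and the missingness mask.
#'
#' @param panel a [MoodPanel-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  T <- nrow(panel); ids <- participantIds(panel)
  cov <- covariates(panel)
  df <- data.frame(id = rep(ids, each = T), week = rep(seq_len(T), length(ids)),
                   cov[rep(seq_along(ids), each = T), , drop = FALSE],
                   row.names = NULL)
  # full double precision so the round trip is bit-exact
  for (v in processNames(panel)) {
    x <- as.vector(scoreMatrix(panel, v))
    df[[v]] <- ifelse(is.na(x), "", sprintf("%.17g", x))
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Apply the study eligibility filters
#'
#' Removes participants with fewer than `minWeeks` non-missing weeks on any
#' modelled outcome and, when `requireVariation`, participants whose
#' non-missing values on any modelled outcome have zero variance (a
#' flat-liner cannot inform within-person dynamics). The exclusion log has
#' one row per removed participant with the reason.
#'
#' @param panel a [MoodPanel-class].
#' @param minWeeks minimum non-missing weeks per outcome (default 20, the
#'   usual intensive-longitudinal-data threshold).
#' @param requireVariation logical; exclude zero-variance series.
#' @param processes outcomes to check (default: all present).
#' @return list with elements `panel` (filtered) and `exclusions`
#'   (data.frame `id`, `reason`).
#' @export
applyEligibility <- function(panel, minWeeks = 20L, requireVariation = TRUE,
                             processes = processNames(panel)) {
  ids <- participantIds(panel)
  reason <- setNames(rep(NA_character_, length(ids)), ids)
  for (v in processes) {
    m <- scoreMatrix(panel, v)
    nObs <- colSums(!is.na(m))
    low <- nObs < minWeeks
    reason[is.na(reason) & low] <- sprintf("fewer than %d weeks on %s",
                                           minWeeks, v)
    if (requireVariation) {
      novar <- vapply(seq_along(ids), function(i) {
        x <- m[!is.na(m[, i]), i]
        length(x) > 0 && var(x) == 0
      }, logical(1))
      reason[is.na(reason) & novar] <- paste("no variation in", v)
    }
  }
  keep <- is.na(reason)
  if (!any(keep))
    stop("no participants satisfy the eligibility filters; ",
         "review minWeeks/requireVariation")
  excl <- data.frame(id = ids[!keep], reason = reason[!keep],
                     row.names = NULL, stringsAsFactors = FALSE)
  list(panel = panel[, keep], exclusions = excl)
}

#' Missing-data summary of a panel
#'
#' @param panel a [MoodPanel-class].
#' @param process outcome whose mask is summarised (default first assay).
#' @return list with `byParticipant` (data.frame `id`, `missingFraction`),
#'   `byWeek` (data.frame `week`, `missingFraction`) and `overall`.
#' @export
missingnessSummary <- function(panel, process = processNames(panel)[1]) {
  m <- is.na(scoreMatrix(panel, process))
  list(byParticipant = data.frame(id = participantIds(panel),
                                  missingFraction = colMeans(m),
                                  row.names = NULL),
       byWeek = data.frame(week = seq_len(nrow(panel)),
                           missingFraction = rowMeans(m)),
       overall = mean(m))
}
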