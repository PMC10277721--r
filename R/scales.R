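## Weekly outcome scores from raw questionnaire items.
##
## QIDS-SR16 items (1-based): 1 sleep onset, 2 sleep maintenance, 3 early
## morning waking, 4 hypersomnia, 5 sad mood, 6 decreased appetite,
## 7 increased appetite, 8 weight decrease, 9 weight increase,
## 10 concentration, 11 self-view, 12 suicidal ideation, 13 interest,
## 14 energy, 15 psychomotor slowing, 16 psychomotor agitation.
## ASRM items: 1 mood, 2 self-confidence, 3 reduced need for sleep,
## 4 speech, 5 activity.

.checkItems <- function(items, n, maxval, what) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (ncol(items) != n)
    stop(sprintf("%s requires exactly %d items, got %d", what, n, ncol(items)),
         call. = FALSE)
  bad <- which(!(items %in% 0:maxval | is.na(items)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("%s item %d out of range 0-%d (value %s)",
                 what, bad[1, 2], maxval, format(items[bad[1, , drop = FALSE]])),
         call. = FALSE)
  rowNA <- rowSums(is.na(items))
  if (any(rowNA > 0 & rowNA < n))
    stop(sprintf("%s: partial item missingness within a week is not allowed",
                 what), call. = FALSE)
  items
}

#' Weekly insomnia score from QIDS items
#'
#' Sums the three QIDS-SR16 insomnia items (difficulty getting to sleep,
#' staying asleep, and early morning waking), giving a 0-9 subscale.
#'
#' @param items a length-16 vector or 16-column matrix of QIDS item responses
#'   (each 0-3; a whole week may be `NA`).
#' @return integer score(s) in 0-9 (`NA` for missing weeks).
#' @examples
#' scoreQidsInsomnia(c(1, 0, 2, rep(0, 13)))
#' @export
scoreQidsInsomnia <- function(items) {
  items <- .checkItems(items, 16L, 3L, "QIDS")
  as.integer(rowSums(items[, 1:3, drop = FALSE]))
}

#' Weekly depression score from QIDS items, insomnia items removed
#'
#' Standard nine-domain QIDS scoring (sleep, mood, appetite/weight,
#' concentration, self-view, suicidality, interest, energy, psychomotor; the
#' appetite/weight, sleep and psychomotor domains score as the maximum of
#' their items) with the three insomnia items excluded so that insomnia can be
#' modelled as a separate process. By default the sleep domain is retained as
#' the hypersomnia item alone, preserving the familiar 0-27 frame; set
#' `sleepDomain = "drop"` to remove the sleep domain entirely (0-24).
#'
#' @inheritParams scoreQidsInsomnia
#' @param sleepDomain `"hypersomnia"` (default) or `"drop"`.
#' @return integer score(s) in 0-27 (or 0-24).
#' @export
scoreQidsDepression <- function(items, sleepDomain = c("hypersomnia", "drop")) {
  sleepDomain <- match.arg(sleepDomain)
  items <- .checkItems(items, 16L, 3L, "QIDS")
  pmax2 <- function(m) do.call(pmax, as.data.frame(m))
  domains <- cbind(
    appetite = pmax2(items[, 6:9, drop = FALSE]),
    mood = items[, 5], concentration = items[, 10],
    selfview = items[, 11], suicidality = items[, 12],
    interest = items[, 13], energy = items[, 14],
    psychomotor = pmax2(items[, 15:16, drop = FALSE]))
  if (sleepDomain == "hypersomnia")
    domains <- cbind(domains, sleep = items[, 4])
  as.integer(rowSums(domains))
}

#' Weekly (hypo)mania score from ASRM items
#'
#' Sums the five ASRM items (each 0-4). In the analysis default the reduced
#' need for sleep item is excluded (range 0-16) so that associations with
#' insomnia cannot be driven by a sleep item inside the mania scale; with
#' `includeSleep = TRUE` the full 0-20 total is returned.
#'
#' @param items a length-5 vector or 5-column matrix of ASRM item responses
#'   (each 0-4; a whole week may be `NA`).
#' @param includeSleep logical; keep the reduced-need-for-sleep item.
#' @param sleepItem index of the reduced-need-for-sleep item (default 3).
#' @return integer score(s).
#' @export
scoreAsrm <- function(items, includeSleep = FALSE, sleepItem = 3L) {
  items <- .checkItems(items, 5L, 4L, "ASRM")
  keep <- if (includeSleep) 1:5 else setdiff(1:5, sleepItem)
  as.integer(rowSums(items[, keep, drop = FALSE]))
}
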