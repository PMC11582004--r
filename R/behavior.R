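#' @keywords internal
DEFAULT_SEQUENCE <- c(4L, 1L, 3L, 2L, 4L)

#' Read a keystroke log
#'
#' Long-format delimited text with header columns `subject`, `session`
#' ("training" or "retest"), `block` (1-based), `t` (seconds from block
#' onset) and `key` (1 = index ... 4 = little finger); one row per press.
#'
#' @param path path to a CSV (or TSV, autodetected by extension) file.
#' @return a data.frame with the five columns above.
#' @export
read_keystroke_log <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  log <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_keystroke_log(log)
}

#' Write a keystroke log
#' @param log keystroke data.frame (see [read_keystroke_log()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_keystroke_log <- function(log, path) {
  utils::write.csv(validate_keystroke_log(log), path, row.names = FALSE)
  invisible(path)
}

validate_keystroke_log <- function(log) {
  need <- c("subject", "session", "block", "t", "key")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("keystroke log missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(log$session %in% c("training", "retest"))) {
    stop("session must be 'training' or 'retest'")
  }
  if (!all(log$key %in% 1:4)) {
    bad <- unique(log$key[!(log$key %in% 1:4)])
    stop("malformed key values (must be 1-4): ", paste(bad, collapse = ", "))
  }
  if (any(log$block < 1)) stop("block indices must be >= 1")
  ord <- order(log$subject, log$session, log$block, log$t)
  log <- log[ord, need]
  by_blk <- interaction(log$subject, log$session, log$block, drop = TRUE)
  inc <- tapply(log$t, by_blk, function(t) all(diff(t) > 0))
  if (!all(inc)) stop("press times must be strictly increasing within a block")
  rownames(log) <- NULL
  log
}

#' Find correct sequence executions in a key stream
#'
#' Greedy non-overlapping left-to-right exact matching of the practised
#' five-item template (default 4-1-3-2-4) in a block's key stream. An
#' erroneous press simply never anchors a match, so a 60-press block yields
#' at most 12 matches. The duration of a match is the time from its first to
#' its last press (four inter-press intervals); the gap preceding the first
#' press of the sequence is not counted.
#'
#' @param times numeric vector of press times (seconds), strictly increasing.
#' @param keys integer vector of pressed keys (1-4), same length.
#' @param template integer vector, the practised sequence.
#' @return data.frame with columns `start`, `end` (1-based press indices) and
#'   `duration` (seconds); zero rows when no match.
#' @export
match_sequences <- function(times, keys, template = DEFAULT_SEQUENCE) {
  if (length(template) != 5L) stop("template must have length 5")
  if (length(times) != length(keys)) stop("times and keys differ in length")
  if (length(keys) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      duration = numeric()))
  }
  if (!all(keys %in% 1:4)) {
    stop("malformed key values (must be 1-4): ",
         paste(unique(keys[!(keys %in% 1:4)]), collapse = ", "))
  }
  if (any(diff(times) <= 0)) stop("press times must be strictly increasing")
  m <- length(template)
  n <- length(keys)
  starts <- integer(0)
  i <- 1L
  while (i <= n - m + 1L) {
    if (all(keys[i:(i + m - 1L)] == template)) {
      starts <- c(starts, i)
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  ends <- starts + m - 1L
  data.frame(start = starts, end = ends,
             duration = times[ends] - times[starts])
}

#' Score one practice block
#'
#' Correct-sequence duration (CSD) is the mean time to execute a correct
#' sequence within the block; accuracy (ACC) is the number of correct
#' sequences divided by the block maximum of 12. The performance index is
#' computed from both via [compute_pi()]. Blocks with no correct sequence
#' have undefined (NA) CSD and PI, never zero.
#'
#' @param matches data.frame from [match_sequences()].
#' @param max_sequences block maximum of correct sequences (12 for a 60-press
#'   block).
#' @param pi_variant passed to [compute_pi()].
#' @return one-row data.frame: `n_correct`, `acc`, `csd`, `pi`.
#' @export
score_block <- function(matches, max_sequences = 12L,
                        pi_variant = c("exp_shift", "exp_minus_one")) {
  n <- nrow(matches)
  csd <- if (n > 0L) mean(matches$duration) else NA_real_
  acc <- n / max_sequences
  pi <- if (is.na(csd)) NA_real_ else compute_pi(csd, acc, pi_variant)
  data.frame(n_correct = n, acc = acc, csd = csd, pi = pi)
}

#' Performance index combining speed and accuracy
#'
#' Composite per-block score `PI = 100 * exp(-CSD) * exp(ACC - 1)` (default
#' parse), strictly decreasing in the correct-sequence duration and strictly
#' increasing in accuracy, with maximum 100 at (CSD -> 0, ACC = 1). The
#' printed formula the index derives from is typographically ambiguous; the
#' alternative reading `100 * exp(-CSD) * (exp(ACC) - 1)` is available via
#' `variant = "exp_minus_one"`.
#'
#' @param csd correct-sequence duration in seconds (>= 0); vectorised.
#' @param acc accuracy in `[0, 1]`; vectorised.
#' @param variant which algebraic parse to use.
#' @return numeric PI values; in (0, 100] under the default parse.
#' @export
compute_pi <- function(csd, acc, variant = c("exp_shift", "exp_minus_one")) {
  variant <- match.arg(variant)
  ok <- is.na(csd) | is.na(acc)
  if (any(csd < 0, na.rm = TRUE)) stop("csd must be >= 0")
  if (any(acc < 0 | acc > 1, na.rm = TRUE)) stop("acc must lie in [0, 1]")
  if (variant == "exp_shift") {
    100 * exp(-csd) * exp(acc - 1)
  } else {
    100 * exp(-csd) * (exp(acc) - 1)
  }
}

#' Score a whole session block by block
#'
#' @param log keystroke data.frame for one subject (may contain both
#'   sessions); see [read_keystroke_log()].
#' @param session which session to score.
#' @param template practised key sequence.
#' @param pi_variant passed to [compute_pi()].
#' @return data.frame with one row per block: `subject`, `session`, `block`,
#'   `n_correct`, `acc`, `csd`, `pi`.
#' @export
score_session <- function(log, session = c("training", "retest"),
                          template = DEFAULT_SEQUENCE,
                          pi_variant = c("exp_shift", "exp_minus_one")) {
  session <- match.arg(session)
  log <- validate_keystroke_log(log)
  log <- log[log$session == session, ]
  if (nrow(log) == 0L) stop("no presses for session '", session, "'")
  subject <- unique(log$subject)
  if (length(subject) != 1L) stop("score_session expects a single subject")
  n_max <- if (session == "training") 18L else 14L
  blocks <- sort(unique(log$block))
  if (length(blocks) > n_max) {
    stop(sprintf("%s session has %d blocks (max %d)", session,
                 length(blocks), n_max))
  }
  out <- do.call(rbind, lapply(blocks, function(b) {
    blk <- log[log$block == b, ]
    sc <- score_block(match_sequences(blk$t, blk$key, template),
                      pi_variant = pi_variant)
    cbind(data.frame(subject = subject, session = session, block = b), sc)
  }))
  rownames(out) <- NULL
  out
}

#' Online and offline learning measures from session curves
#'
#' BoT (beginning of training) is the mean PI of training blocks 1-2, EoT
#' (end of training) the mean PI of blocks 15-18, BoR (beginning of retest)
#' the mean PI of retest blocks 1-2. Online learning = EoT - BoT; offline
#' consolidation = BoR - EoT. When exactly one of the two initial retest
#' blocks has no correct sequence (undefined PI), the missing value is
#' imputed by the other block's PI and the outcome is flagged; when both are
#' undefined the outcome is flagged invalid.
#'
#' @param training session curve data.frame from [score_session()], 18 blocks.
#' @param retest session curve data.frame, at least 2 blocks.
#' @return one-row data.frame: `subject`, `bot`, `eot`, `bor`, `online`,
#'   `offline`, `imputed_bor`, `valid`.
#' @export
learning_metrics <- function(training, retest) {
  if (nrow(training) != 18L) {
    stop("training session must have 18 scored blocks, got ", nrow(training))
  }
  if (nrow(retest) < 2L) stop("retest session must have at least 2 blocks")
  training <- training[order(training$block), ]
  retest <- retest[order(retest$block), ]
  bot <- mean(training$pi[1:2])
  eot <- mean(training$pi[15:18])
  r2 <- retest$pi[1:2]
  imputed <- FALSE
  valid <- TRUE
  if (all(is.na(r2))) {
    valid <- FALSE
    bor <- NA_real_
  } else if (any(is.na(r2))) {
    bor <- r2[!is.na(r2)]
    imputed <- TRUE
  } else {
    bor <- mean(r2)
  }
  data.frame(subject = training$subject[1L],
             bot = bot, eot = eot, bor = bor,
             online = eot - bot, offline = bor - eot,
             imputed_bor = imputed, valid = valid)
}

#' Upper-extremity sub-score (UES)
#'
#' Sum of the four MDS-UPDRS III items most relevant to sequential
#' finger-tapping with the task-performing hand: rigidity, finger tapping,
#' hand movements and pronation-supination movements. Each item is rated
#' 0-4, so the score ranges from 0 to 16 with higher values indicating
#' greater motor symptom severity.
#'
#' @param rigidity,finger_tapping,hand_movements,pronation_supination item
#'   ratings, integers 0-4 (vectorised).
#' @return integer UES in `[0, 16]`.
#' @export
ues_score <- function(rigidity, finger_tapping, hand_movements,
                      pronation_supination) {
  items <- cbind(rigidity, finger_tapping, hand_movements,
                 pronation_supination)
  if (any(items < 0 | items > 4 | items != round(items))) {
    stop("each UES item must be an integer in [0, 4]")
  }
  as.integer(rowSums(items))
}
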