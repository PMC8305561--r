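#' Construct a two-arm pre-post trial
#'
#' A `prepost_trial` holds complete subject-level records from a two-arm
#' randomized trial with one baseline and one post-treatment measurement:
#' a subject identifier, a binary arm indicator (0 = control, 1 = treatment),
#' the baseline value `y_pre` and the post-treatment value `y_post`, both on
#' the same outcome scale.
#'
#' Records with a missing measurement are rejected rather than dropped:
#' all analyses in this package are defined for complete cases only, and a
#' silent drop would change the design quantities `n0`, `n1`.
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param arm arm indicator; integers in `{0, 1}` or the strings
#'   `"control"` / `"treatment"` (mapped to 0/1 with a message).
#' @param y_pre,y_post numeric baseline and post-treatment measurements.
#' @return A data frame of class `prepost_trial` with columns
#'   `subject_id`, `arm`, `y_pre`, `y_post`.
#' @examples
#' prepost_trial(c("a", "b", "c", "d"), c(0, 0, 1, 1),
#'               c(88, 90, 87, 89), c(86, 88, 83, 84))
#' @export
prepost_trial <- function(subject_id, arm, y_pre, y_post) {
  if (is.character(arm) || is.factor(arm)) {
    arm <- as.character(arm)
    known <- c(control = 0, treatment = 1, "0" = 0, "1" = 1)
    if (!all(arm %in% names(known))) {
      stop("`arm` strings must be 'control'/'treatment' (or '0'/'1'), got: ",
           paste(unique(setdiff(arm, names(known))), collapse = ", "),
           call. = FALSE)
    }
    if (any(arm %in% c("control", "treatment"))) {
      message("mapping arm labels control->0, treatment->1")
    }
    arm <- unname(known[arm])
  }
  df <- data.frame(subject_id = as.character(subject_id),
                   arm = as.integer(arm),
                   y_pre = as.numeric(y_pre),
                   y_post = as.numeric(y_post),
                   stringsAsFactors = FALSE)
  validate_trial(df)
}

validate_trial <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "arm", "y_pre", "y_post")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  if (nrow(df) == 0L) stop("trial has no records", call. = FALSE)
  if (anyNA(df$y_pre) || anyNA(df$y_post)) {
    bad <- df$subject_id[is.na(df$y_pre) | is.na(df$y_post)]
    stop("incomplete records (missing y_pre or y_post) for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(df$arm %in% c(0L, 1L))) {
    stop("arm values must be 0 (control) or 1 (treatment); found: ",
         paste(unique(setdiff(df$arm, 0:1)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicated subject_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  n_arm <- table(factor(df$arm, levels = 0:1))
  if (any(n_arm < 2L)) {
    stop("each arm needs at least 2 subjects; got n0 = ", n_arm[["0"]],
         ", n1 = ", n_arm[["1"]], call. = FALSE)
  }
  class(df) <- c("prepost_trial", "data.frame")
  df
}

#' @export
print.prepost_trial <- function(x, ...) {
  n <- arm_sizes(x)
  cat(sprintf("<prepost_trial> %d subjects (n0 = %d control, n1 = %d treatment)\n",
              nrow(x), n[1], n[2]))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

arm_sizes <- function(trial) {
  c(n0 = sum(trial$arm == 0L), n1 = sum(trial$arm == 1L))
}

#' Read a pre-post trial from CSV
#'
#' Two layouts are supported.  *Wide*: one row per subject with columns
#' `subject_id, arm, y_pre, y_post`.  *Long*: one row per measurement with
#' columns `subject_id, arm, time, y`, where `time` is coded 0 (baseline)
#' and 1 (post-treatment) and every subject must appear at both times.
#' Files are comma-separated with a header row, UTF-8, `.` decimal mark.
#'
#' @param path path to a CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @return A validated [prepost_trial].
#' @seealso [write_trial()]
#' @export
read_trial <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, encoding = "UTF-8")
  if (layout == "wide") {
    need <- c("subject_id", "arm", "y_pre", "y_post")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("wide CSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    out <- df[need]
  } else {
    need <- c("subject_id", "arm", "time", "y")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("long CSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!all(df$time %in% c(0L, 1L))) {
      stop("long layout requires time coded 0 (baseline) / 1 (post)",
           call. = FALSE)
    }
    ids <- unique(df$subject_id)
    pre  <- df[df$time == 0L, ]
    post <- df[df$time == 1L, ]
    bad <- ids[!(ids %in% pre$subject_id) | !(ids %in% post$subject_id) |
               ids %in% pre$subject_id[duplicated(pre$subject_id)] |
               ids %in% post$subject_id[duplicated(post$subject_id)]]
    if (length(bad)) {
      stop("incomplete long records (need exactly one row per time) for ",
           "subject(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    m <- match(ids, pre$subject_id)
    out <- data.frame(subject_id = as.character(ids),
                      arm = pre$arm[m],
                      y_pre = pre$y[m],
                      y_post = post$y[match(ids, post$subject_id)],
                      stringsAsFactors = FALSE)
    in_both <- df$arm[match(ids, df$subject_id)]
    if (!identical(as.integer(out$arm), as.integer(in_both))) {
      stop("arm differs between time points for some subject", call. = FALSE)
    }
  }
  tr <- prepost_trial(out$subject_id, out$arm, out$y_pre, out$y_post)
  message(sprintf("read %d subjects (%s layout) from %s",
                  nrow(tr), layout, path))
  tr
}

#' Write a pre-post trial to CSV
#'
#' Numeric values are written with 17 significant digits so that
#' `read_trial(write_trial(x))` reproduces `x` bit-identically.
#'
#' @param trial a [prepost_trial].
#' @inheritParams read_trial
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  trial <- validate_trial(trial)
  num <- function(x) sprintf("%.17g", x)
  if (layout == "wide") {
    out <- data.frame(subject_id = trial$subject_id, arm = trial$arm,
                      y_pre = num(trial$y_pre), y_post = num(trial$y_post),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      subject_id = rep(trial$subject_id, each = 2L),
      arm = rep(trial$arm, each = 2L),
      time = rep(c(0L, 1L), nrow(trial)),
      y = num(as.vector(rbind(trial$y_pre, trial$y_post))),
      stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Per-arm summary statistics of a trial
#'
#' Computes, for each arm, the sample size, baseline and post-treatment
#' means and standard deviations (denominator `n_j - 1`), and the pre-post
#' sample correlation, plus the pooled baseline mean and SD over all
#' subjects.  These are the sample analogues of the population parameters
#' used by the closed-form variance formulas in [true_variance()].
#'
#' @param trial a [prepost_trial].
#' @return An object of class `trial_summary`: a list with components
#'   `arms` (data frame, one row per arm: `arm`, `n`, `mean_pre`,
#'   `mean_post`, `sd_pre`, `sd_post`, `r`) and `pooled`
#'   (`mean_pre`, `sd_pre`, `n`).
#' @export
trial_summary <- function(trial) {
  trial <- validate_trial(trial)
  rows <- lapply(0:1, function(j) {
    d <- trial[trial$arm == j, ]
    if (stats::sd(d$y_pre) == 0) {
      stop("degenerate data: zero baseline variance in arm ", j,
           " (baseline-adjusted regressions undefined)", call. = FALSE)
    }
    data.frame(arm = j, n = nrow(d),
               mean_pre = mean(d$y_pre), mean_post = mean(d$y_post),
               sd_pre = stats::sd(d$y_pre), sd_post = stats::sd(d$y_post),
               r = if (stats::sd(d$y_post) > 0)
                     stats::cor(d$y_pre, d$y_post) else NA_real_)
  })
  out <- list(arms = do.call(rbind, rows),
              pooled = list(mean_pre = mean(trial$y_pre),
                            sd_pre = stats::sd(trial$y_pre),
                            n = nrow(trial)))
  class(out) <- "trial_summary"
  out
}

#' @export
summary.prepost_trial <- function(object, ...) trial_summary(object)

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary>\n")
  print(x$arms, row.names = FALSE, digits = 4)
  cat(sprintf("pooled baseline: mean %.4g, sd %.4g (n = %d)\n",
              x$pooled$mean_pre, x$pooled$sd_pre, x$pooled$n))
  invisible(x)
}
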