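#' Build a randomized verbal n-back task schedule
#'
#' Constructs the letter sequence for a two-condition (0-back / 2-back) verbal
#' n-back task. Each condition is measured in `blocks_per_condition` blocks of
#' `block_length` stimuli with exactly `targets_per_block` targets per block.
#' In the 0-back condition the target is any occurrence of the letter "x"; in
#' the 2-back condition a target is a letter identical to the letter two
#' positions back. Lure trials -- nontarget stimuli whose letter matches the
#' letter one or three positions back -- are placed so that the 2-back
#' condition contains exactly `lure_count` of them (the default 15 of 84
#' stimuli, i.e. a 17.9% lure frequency).
#'
#' @param blocks_per_condition Number of blocks per condition (default 6).
#' @param block_length Stimuli per block (default 14).
#' @param targets_per_block Targets per block (default 3).
#' @param lure_count Total number of lure trials in the 2-back condition
#'   (default 15).
#' @param seed Integer seed for reproducible randomization, or `NULL`.
#' @param max_tries Bounded number of per-block construction retries before
#'   the constraint set is declared infeasible.
#' @return A data.frame of class `wmn_schedule` with one row per stimulus and
#'   columns `trial`, `block`, `condition`, `letter`, `is_target`, `is_lure`.
#' @examples
#' sch <- build_schedule(seed = 1)
#' table(sch$condition, sch$is_target)
#' @export
build_schedule <- function(blocks_per_condition = 6, block_length = 14,
                           targets_per_block = 3, lure_count = 15,
                           seed = NULL, max_tries = 500) {
  stopifnot(blocks_per_condition >= 1, block_length >= 3,
            targets_per_block >= 1, lure_count >= 0)
  if (targets_per_block >= block_length) {
    stop("targets_per_block must be smaller than block_length", call. = FALSE)
  }
  # 2-back targets need positions >= 3; positions 1 and 2 are always
  # nontargets and position 1 can never be a lure (no preceding letter).
  lure_capacity <- blocks_per_condition *
    (block_length - targets_per_block - 1L)
  if (lure_count > lure_capacity) {
    stop(sprintf("infeasible lure constraint: requested %d lures, capacity %d",
                 lure_count, lure_capacity), call. = FALSE)
  }

  with_seed(seed, {
    alphabet <- setdiff(letters, "x")

    # Distribute the lure quota over 2-back blocks without exceeding any
    # block's capacity (multivariate hypergeometric draw over block slots).
    cap <- block_length - targets_per_block - 1L
    slots <- rep(seq_len(blocks_per_condition), each = cap)
    quota <- tabulate(sample(slots, lure_count), blocks_per_condition)

    build_2back_block <- function(n_lures) {
      for (try in seq_len(max_tries)) {
        target_pos <- sort(sample(3:block_length, targets_per_block))
        open <- setdiff(2:block_length, target_pos)
        lure_pos <- if (n_lures > 0) sort(sample(open, n_lures)) else integer(0)
        seq_letters <- character(block_length)
        ok <- TRUE
        for (i in seq_len(block_length)) {
          back2 <- if (i > 2) seq_letters[i - 2] else NA_character_
          back1 <- if (i > 1) seq_letters[i - 1] else NA_character_
          back3 <- if (i > 3) seq_letters[i - 3] else NA_character_
          if (i %in% target_pos) {
            seq_letters[i] <- back2
          } else if (i %in% lure_pos) {
            cand <- setdiff(stats::na.omit(c(back1, back3)), back2)
            if (length(cand) == 0) { ok <- FALSE; break }
            seq_letters[i] <- if (length(cand) == 1) cand else sample(cand, 1)
          } else {
            cand <- setdiff(alphabet, stats::na.omit(c(back1, back2, back3)))
            seq_letters[i] <- sample(cand, 1)
          }
        }
        if (!ok) next
        is_target <- vapply(seq_len(block_length), function(i) {
          i > 2 && seq_letters[i] == seq_letters[i - 2]
        }, logical(1))
        is_lure <- vapply(seq_len(block_length), function(i) {
          if (is_target[i]) return(FALSE)
          (i > 1 && seq_letters[i] == seq_letters[i - 1]) ||
            (i > 3 && seq_letters[i] == seq_letters[i - 3])
        }, logical(1))
        if (sum(is_target) == targets_per_block &&
            identical(which(is_target), target_pos) &&
            sum(is_lure) == n_lures) {
          return(data.frame(letter = seq_letters, is_target = is_target,
                            is_lure = is_lure, stringsAsFactors = FALSE))
        }
      }
      stop("could not satisfy lure/target constraints within retry budget",
           call. = FALSE)
    }

    build_0back_block <- function() {
      target_pos <- sort(sample(seq_len(block_length), targets_per_block))
      seq_letters <- sample(alphabet, block_length, replace = TRUE)
      seq_letters[target_pos] <- "x"
      data.frame(letter = seq_letters,
                 is_target = seq_len(block_length) %in% target_pos,
                 is_lure = FALSE, stringsAsFactors = FALSE)
    }

    condition_order <- sample(rep(c("0back", "2back"),
                                  each = blocks_per_condition))
    lure_iter <- 0L
    blocks <- lapply(seq_along(condition_order), function(b) {
      cond <- condition_order[b]
      blk <- if (cond == "2back") {
        lure_iter <<- lure_iter + 1L
        build_2back_block(quota[lure_iter])
      } else {
        build_0back_block()
      }
      blk$block <- b
      blk$condition <- cond
      blk
    })
    out <- do.call(rbind, blocks)
    out$trial <- seq_len(nrow(out))
    out <- out[, c("trial", "block", "condition", "letter",
                   "is_target", "is_lure")]
    attr(out, "params") <- list(blocks_per_condition = blocks_per_condition,
                                block_length = block_length,
                                targets_per_block = targets_per_block,
                                lure_count = lure_count, seed = seed)
    class(out) <- c("wmn_schedule", "data.frame")
    out
  })
}

#' Score one n-back condition as a signal-detection D-prime
#'
#' Computes d' = qnorm(H) - qnorm(F), where H is the hit rate over target
#' stimuli and F the false-alarm rate over nontarget stimuli, counting only
#' non-missing responses. Extreme proportions are corrected cell-wise:
#' a proportion of 0 is replaced by `0.5/N` and a proportion of 1 by
#' `(N - 0.5)/N`, with N the number of non-missing trials in that cell. With
#' the default schedule (18 targets, 66 nontargets per condition) a perfect
#' responder therefore scores `qnorm(17.5/18) - qnorm(0.5/66) = 4.34`.
#'
#' @param responses A data.frame with a `response` column
#'   (`"target"`/`"nontarget"`/`NA`) aligned row-by-row with `schedule`, or
#'   such a character vector.
#' @param schedule A `wmn_schedule` (see [build_schedule()]).
#' @param condition Which condition to score, e.g. `"2back"`.
#' @return The d-prime value (scalar).
#' @export
score_dprime <- function(responses, schedule, condition) {
  resp <- if (is.data.frame(responses)) responses$response else responses
  stopifnot(length(resp) == nrow(schedule))
  if (!condition %in% schedule$condition) {
    stop(sprintf("condition '%s' not present in schedule", condition),
         call. = FALSE)
  }
  keep <- schedule$condition == condition & !is.na(resp)
  tgt <- keep & schedule$is_target
  non <- keep & !schedule$is_target
  n_t <- sum(tgt)
  n_n <- sum(non)
  if (n_t == 0 || n_n == 0) {
    stop("d-prime undefined: no non-missing target or nontarget trials",
         call. = FALSE)
  }
  correct_extreme <- function(count, n) {
    if (count == 0) return(0.5 / n)
    if (count == n) return((n - 0.5) / n)
    count / n
  }
  hit_rate <- correct_extreme(sum(resp[tgt] == "target"), n_t)
  fa_rate <- correct_extreme(sum(resp[non] == "target"), n_n)
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Apply response- and distribution-based subject exclusions
#'
#' Flags subjects for exclusion according to five rules: (a) missing responses
#' in more than `missing_frac` of all stimuli of the task; (b) more than
#' `missing_frac` of target stimuli missing in at least `min_blocks` blocks;
#' (c) the same for nontarget stimuli; (d) any cognitive measure lying more
#' than `sd_limit` standard deviations above or below the sample mean
#' (mean and SD computed once, on the pre-exclusion sample); (e) incomplete
#' behavioral data (any missing cognitive measure). Rules (a)-(c) require
#' response logs.
#'
#' @param table A behavioral data.frame, one row per subject.
#' @param logs Optional list of response data.frames (one per subject, aligned
#'   with `schedule`), each with a `response` column.
#' @param schedule The task schedule the logs refer to.
#' @param cognitive_vars Columns of `table` treated as cognitive measures for
#'   rules (d) and (e).
#' @param missing_frac Missingness fraction threshold (default 0.3).
#' @param min_blocks Number of affected blocks required for rules (b)/(c).
#' @param sd_limit Outlier threshold in SD units (default 4).
#' @return `table` with added logical column `excluded` and character column
#'   `exclusion_reasons` (comma-separated codes among "a".."e").
#' @export
apply_exclusions <- function(table, logs = NULL, schedule = NULL,
                             cognitive_vars = c("d_prime_2back",
                                                "d_prime_0back",
                                                "rt_difference",
                                                "episodic_memory",
                                                "item_familiarity"),
                             missing_frac = 0.3, min_blocks = 3,
                             sd_limit = 4) {
  n <- nrow(table)
  reasons <- vector("list", n)
  cognitive_vars <- intersect(cognitive_vars, names(table))

  if (!is.null(logs)) {
    stopifnot(!is.null(schedule), length(logs) == n)
    for (i in seq_len(n)) {
      resp <- logs[[i]]$response
      stopifnot(length(resp) == nrow(schedule))
      miss <- is.na(resp)
      if (mean(miss) > missing_frac) reasons[[i]] <- c(reasons[[i]], "a")
      blk_frac <- function(sel) {
        vapply(split(miss[sel], schedule$block[sel]), mean, numeric(1))
      }
      if (sum(blk_frac(schedule$is_target) > missing_frac) >= min_blocks) {
        reasons[[i]] <- c(reasons[[i]], "b")
      }
      if (sum(blk_frac(!schedule$is_target) > missing_frac) >= min_blocks) {
        reasons[[i]] <- c(reasons[[i]], "c")
      }
    }
  }

  # Rule (d): single-pass 4-SD screen on the pre-exclusion sample.
  for (v in cognitive_vars) {
    x <- table[[v]]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    out <- which(!is.na(x) & abs(x - mu) > sd_limit * s)
    for (i in out) reasons[[i]] <- c(reasons[[i]], "d")
  }

  # Rule (e): incomplete behavioral data.
  if (length(cognitive_vars) > 0) {
    incomplete <- which(rowSums(is.na(table[, cognitive_vars,
                                            drop = FALSE])) > 0)
    for (i in incomplete) reasons[[i]] <- c(reasons[[i]], "e")
  }

  table$excluded <- vapply(reasons, function(r) length(r) > 0, logical(1))
  table$exclusion_reasons <- vapply(reasons, function(r) {
    paste(sort(unique(r)), collapse = ",")
  }, character(1))
  table
}

#' Residualize a vector on categorical batch factors and standardize
#'
#' Ordinary least-squares residuals from regressing `values` on indicator
#' variables for the supplied factors, scaled afterwards to mean 0 and
#' variance 1. With a single-level factor (or no factors) this reduces to
#' plain z-scoring. If the factors explain the values exactly, the residuals
#' are degenerate; a warning is issued and a zero vector returned.
#'
#' @param values Numeric vector, one entry per subject.
#' @param factors A factor, or a data.frame of factors, aligned with `values`;
#'   `NULL` for intercept-only.
#' @return Standardized residual vector.
#' @export
residualize <- function(values, factors = NULL) {
  stopifnot(is.numeric(values))
  if (stats::sd(values) < .Machine$double.eps^0.5) {
    stop("degenerate input: values vector is constant", call. = FALSE)
  }
  if (is.null(factors)) {
    return(zscore(values))
  }
  fdf <- if (is.data.frame(factors)) factors else data.frame(f = factors)
  fdf[] <- lapply(fdf, function(f) factor(f))
  used <- fdf[, vapply(fdf, nlevels, integer(1)) > 1, drop = FALSE]
  if (ncol(used) == 0) {
    return(zscore(values))
  }
  for (v in names(used)) {
    if (any(table(used[[v]]) < 2)) {
      stop(sprintf("factor '%s' has levels with fewer than 2 subjects", v),
           call. = FALSE)
    }
  }
  mm <- stats::model.matrix(~ ., data = used)
  res <- stats::lm.fit(mm, values)$residuals
  if (stats::sd(res) < .Machine$double.eps^0.5) {
    warning("residual variance is degenerate (factors explain values exactly)",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  zscore(res)
}

#' Residualize every voxel of a contrast matrix on batch factors
#'
#' Applies the same OLS batch-residualization as [residualize()] to each voxel
#' column of a subjects-by-voxels matrix in one pass, returning standardized
#' residuals (each voxel column mean 0, variance 1).
#'
#' @param values Subjects x voxels numeric matrix (or a `contrast_matrix`).
#' @param factors Data.frame of categorical batch factors, one row per
#'   subject.
#' @return Matrix of standardized residuals with the input dimensions; if a
#'   `contrast_matrix` was supplied, one is returned.
#' @export
residualize_matrix <- function(values, factors) {
  cm <- NULL
  if (inherits(values, "contrast_matrix")) {
    cm <- values
    values <- cm$values
  }
  fdf <- if (is.data.frame(factors)) factors else data.frame(f = factors)
  fdf[] <- lapply(fdf, factor)
  used <- fdf[, vapply(fdf, nlevels, integer(1)) > 1, drop = FALSE]
  mm <- if (ncol(used) > 0) {
    stats::model.matrix(~ ., data = used)
  } else {
    matrix(1, nrow(values), 1)
  }
  qr_mm <- qr(mm)
  res <- values - qr.fitted(qr_mm, values)
  sds <- apply(res, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    stop("degenerate residual variance in at least one voxel", call. = FALSE)
  }
  out <- scale(res)
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  if (!is.null(cm)) {
    cm$values <- out
    return(cm)
  }
  out
}
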