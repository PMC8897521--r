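#' Generate a visual-search trial schedule
#'
#' Builds the block structure of the search task: each block mixes Exemplar
#' Match trials (the exact target is present), Foil trials (a same-category
#' non-target is present) and Target Absent trials.  Item sides are balanced
#' left/right within block for the two item-present trial types, the side of
#' the patterned symbol stream is fixed per participant, and the length of
#' the preceding symbol pattern phase (1, 2 or 3 triplets, i.e. 3, 6 or 9
#' symbols) is drawn uniformly per trial.
#'
#' @param n_blocks Number of blocks (default 7).
#' @param trials_per_block Named integer vector giving per-block counts for
#'   `exemplar_match`, `foil` and `target_absent` (defaults 28/28/4).  The
#'   item-present counts must be even so the left/right split is exact.
#' @param pattern_side `"left"` or `"right"`: the screen side that carries
#'   the structured symbol triplets, constant for the participant.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A data frame with one row per trial: `block_index`, `trial_index`
#'   (within block, after randomization), `trial_type`, `item_side`
#'   (`"none"` for target-absent trials), `pattern_side`, `symbol_count`,
#'   and empty behavioral columns `response`, `correct`, `rt_ms` to be
#'   filled by [simulate_behavior()].
#' @seealso [simulate_epochs()], [simulate_behavior()]
#' @examples
#' sched <- generate_design(n_blocks = 2, pattern_side = "left", seed = 1)
#' table(sched$trial_type, sched$item_side)
#' @export
generate_design <- function(n_blocks = 7,
                            trials_per_block = c(exemplar_match = 28,
                                                 foil = 28,
                                                 target_absent = 4),
                            pattern_side = c("left", "right"),
                            seed = NULL) {
  pattern_side <- match.arg(pattern_side)
  stopifnot(n_blocks >= 1)
  need <- c("exemplar_match", "foil", "target_absent")
  if (!all(need %in% names(trials_per_block))) {
    stop("trials_per_block must name counts for: ",
         paste(need, collapse = ", "))
  }
  counts <- trials_per_block[need]
  if (any(counts < 0)) stop("trial counts must be non-negative")
  if (counts[["exemplar_match"]] %% 2L != 0L || counts[["foil"]] %% 2L != 0L) {
    stop("exemplar_match and foil counts must be even: the design splits ",
         "item sides 50/50 left-right within each block")
  }
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      type <- c(rep("exemplar_match", counts[["exemplar_match"]]),
                rep("foil", counts[["foil"]]),
                rep("target_absent", counts[["target_absent"]]))
      side <- c(rep(c("left", "right"), each = counts[["exemplar_match"]] / 2),
                rep(c("left", "right"), each = counts[["foil"]] / 2),
                rep("none", counts[["target_absent"]]))
      ord <- sample.int(length(type))
      data.frame(
        block_index = b,
        trial_index = seq_along(type),
        trial_type = type[ord],
        item_side = side[ord],
        pattern_side = pattern_side,
        symbol_count = sample(c(3L, 6L, 9L), length(type), replace = TRUE),
        response = "none",
        correct = NA,
        rt_ms = NA_real_,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, blocks)
  })
}

#' Default symbol alphabet and triplet inventory
#'
#' The task uses an 18-symbol alphabet: nine symbols are grouped into three
#' fixed, ordered triplets that make up the patterned stream, and the nine
#' remaining symbols feed the unstructured random stream (disjoint sets).
#'
#' @return A list with `alphabet` (18 symbol ids), `triplets` (list of 3
#'   character vectors of length 3) and `random_pool` (the 9 symbols not
#'   used in triplets).
#' @export
default_symbol_inventory <- function() {
  alphabet <- sprintf("S%02d", 1:18)
  list(
    alphabet = alphabet,
    triplets = list(alphabet[1:3], alphabet[4:6], alphabet[7:9]),
    random_pool = alphabet[10:18]
  )
}

#' Generate one pattern-phase symbol stream
#'
#' A patterned stream is a concatenation of whole triplets drawn from the
#' participant's triplet inventory; a random stream is a pseudo-random
#' sequence from the non-triplet pool with back-to-back repeats forbidden.
#'
#' @param n_triplets 1, 2 or 3 (3, 6 or 9 symbols).
#' @param mode `"patterned"` or `"random"`.
#' @param inventory Symbol inventory as from [default_symbol_inventory()].
#' @param seed Integer seed.
#' @return A list of class `symbol_sequence`: `mode`, `symbols`, and (for
#'   patterned streams) `triplet_inventory`.
#' @export
generate_symbol_stream <- function(n_triplets, mode = c("patterned", "random"),
                                   inventory = default_symbol_inventory(),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!n_triplets %in% c(1L, 2L, 3L)) {
    stop("n_triplets must be 1, 2 or 3")
  }
  n_sym <- 3L * as.integer(n_triplets)
  with_seed(seed, {
    if (mode == "patterned") {
      # Triplet order is sampled uniformly with replacement per phase: the
      # triplets themselves are consistent, their order is not a super-pattern.
      pick <- sample.int(length(inventory$triplets), n_triplets, replace = TRUE)
      symbols <- unlist(inventory$triplets[pick], use.names = FALSE)
    } else {
      pool <- inventory$random_pool
      symbols <- character(n_sym)
      symbols[1] <- sample(pool, 1L)
      for (i in seq_len(n_sym - 1L) + 1L) {
        symbols[i] <- sample(setdiff(pool, symbols[i - 1L]), 1L)
      }
    }
    structure(
      list(mode = mode, symbols = symbols,
           triplet_inventory = if (mode == "patterned") inventory$triplets),
      class = "symbol_sequence"
    )
  })
}

#' Duration of a pattern phase
#'
#' Each symbol is shown for a fixed duration (400 ms by default), so a phase
#' of `n_triplets` triplets (3 symbols each) lasts
#' `3 * n_triplets * symbol_duration_ms`; three triplets last 3600 ms.
#'
#' @param n_triplets Number of triplets (>= 1).
#' @param symbol_duration_ms Per-symbol display duration in ms (> 0).
#' @return Duration in ms.
#' @export
pattern_phase_duration <- function(n_triplets, symbol_duration_ms = 400) {
  stopifnot(n_triplets >= 1)
  if (symbol_duration_ms <= 0) stop("symbol_duration_ms must be positive")
  3 * n_triplets * symbol_duration_ms
}

#' Simulate search-task behavior (responses, accuracy, reaction times)
#'
#' Fills the behavioral columns of a schedule from a log-normal RT model and
#' per-trial-type accuracy probabilities.  Sampled RTs beyond the response
#' deadline become omissions: `rt_ms` missing, `response = "none"`,
#' `correct = FALSE`.  Correctness is scored against the present/absent
#' ground truth of the trial type (target present only on Exemplar Match
#' trials).
#'
#' @param schedule Schedule from [generate_design()].
#' @param rt_model Named list (one entry per trial type) of lists with
#'   `mean_ms` (arithmetic mean RT), `sdlog` (log-scale sd) and `p_correct`.
#' @param deadline_ms Response deadline (default 1600 ms).
#' @param seed Integer seed.
#' @return The schedule with `response`, `correct`, `rt_ms` filled.
#' @export
simulate_behavior <- function(schedule,
                              rt_model = default_rt_model(),
                              deadline_ms = 1600,
                              seed = NULL) {
  types <- unique(schedule$trial_type)
  if (!all(types %in% names(rt_model))) {
    stop("rt_model lacks entries for: ",
         paste(setdiff(types, names(rt_model)), collapse = ", "))
  }
  p <- vapply(rt_model, function(m) m$p_correct, numeric(1))
  if (any(p < 0 | p > 1)) stop("p_correct values must lie in [0, 1]")
  with_seed(seed, {
    n <- nrow(schedule)
    truth_present <- schedule$trial_type == "exemplar_match"
    correct_resp <- ifelse(truth_present, "present", "absent")
    wrong_resp <- ifelse(truth_present, "absent", "present")
    for (ty in types) {
      sel <- which(schedule$trial_type == ty)
      m <- rt_model[[ty]]
      sdlog <- m$sdlog %||% 0.2
      meanlog <- log(m$mean_ms) - sdlog^2 / 2
      rt <- stats::rlnorm(length(sel), meanlog, sdlog)
      hit <- stats::runif(length(sel)) < m$p_correct
      timed_out <- rt > deadline_ms
      schedule$rt_ms[sel] <- ifelse(timed_out, NA_real_, rt)
      schedule$response[sel] <- ifelse(timed_out, "none",
                                       ifelse(hit, correct_resp[sel],
                                              wrong_resp[sel]))
      schedule$correct[sel] <- !timed_out & hit
    }
    schedule
  })
}

#' Default behavioral model parameters
#'
#' Mean RTs echo the study's behavioral pattern (Exemplar Match faster than
#' Foil, both far below the deadline) with near-ceiling accuracy.
#'
#' @return Named list of per-trial-type RT/accuracy parameters.
#' @export
default_rt_model <- function() {
  list(
    exemplar_match = list(mean_ms = 616, sdlog = 0.2, p_correct = 0.96),
    foil           = list(mean_ms = 660, sdlog = 0.2, p_correct = 0.95),
    target_absent  = list(mean_ms = 700, sdlog = 0.2, p_correct = 0.95)
  )
}

#' Simulate the two-alternative forced-choice recognition test
#'
#' After the search task, participants pick which of two symbol groupings
#' "belongs together" (true triplet vs random grouping) over 60 trials and
#' rate confidence on a 1-4 scale.
#'
#' @param n_trials Number of 2AFC trials (default 60).
#' @param p_correct Probability of choosing the true triplet.
#' @param confidence_probs Length-4 probability vector over ratings 1-4.
#' @param seed Integer seed.
#' @return Data frame with `choice_correct` (logical) and `confidence`
#'   (integer 1-4).
#' @export
simulate_2afc <- function(n_trials = 60, p_correct = 0.5,
                          confidence_probs = c(0.1, 0.3, 0.4, 0.2),
                          seed = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (p_correct < 0 || p_correct > 1) stop("p_correct must lie in [0, 1]")
  stopifnot(length(confidence_probs) == 4L, all(confidence_probs >= 0),
            sum(confidence_probs) > 0)
  with_seed(seed, {
    data.frame(
      choice_correct = stats::runif(n_trials) < p_correct,
      confidence = sample(1:4, n_trials, replace = TRUE,
                          prob = confidence_probs)
    )
  })
}
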