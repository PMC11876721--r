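#' Specify a cued repetition-probability design
#'
#' Describes the S1 -> S2 paired-stimulus design in which a subcategory of
#' the first stimulus (S1) cues the probability that the second stimulus
#' (S2) repeats it. Condition cells are allocated with exact counts (not
#' per-trial Bernoulli draws), so every probability must yield an integral
#' number of trials per cell; violations raise an error naming the cell.
#'
#' With the defaults (480 trials per category, equiprobable cues, repetition
#' probabilities 0.75 given a high-repetition cue and 0.25 given a
#' low-repetition cue) each category contains 180 expected repetitions,
#' 180 expected alternations, 60 unexpected repetitions and 60 unexpected
#' alternations, of which 20% are target trials.
#'
#' @param categories Character vector of stimulus category labels.
#' @param trials_per_category Trials per category block.
#' @param p_rep_given_highcue,p_rep_given_lowcue Conditional repetition
#'   probabilities for the two cue levels, in `[0, 1]`.
#' @param target_fraction Proportion of target (response) trials.
#' @param n_stimuli_per_subcategory Size of each S1 stimulus pool.
#' @param seed Integer seed controlling trial order and stimulus assignment.
#' @return A `design_spec` list.
#' @examples
#' spec <- design_spec()
#' trials <- build_category_trials(spec, "word")
#' table(condition_of(trials))
#' @export
design_spec <- function(categories = c("word", "face", "animal"),
                        trials_per_category = 480,
                        p_rep_given_highcue = 0.75,
                        p_rep_given_lowcue = 0.25,
                        target_fraction = 0.20,
                        n_stimuli_per_subcategory = 60,
                        seed = 1L) {
  if (length(categories) < 1 || anyDuplicated(categories) > 0) {
    rlang::abort("`categories` must be a non-empty vector of unique labels")
  }
  for (p in c(p_rep_given_highcue, p_rep_given_lowcue, target_fraction)) {
    if (!is.finite(p) || p < 0 || p > 1) rlang::abort("probabilities must lie in [0, 1]")
  }
  if (trials_per_category < 1) rlang::abort("`trials_per_category` must be positive")
  spec <- list(
    categories = as.character(categories),
    trials_per_category = as.integer(trials_per_category),
    p_rep_given_highcue = p_rep_given_highcue,
    p_rep_given_lowcue = p_rep_given_lowcue,
    target_fraction = target_fraction,
    n_stimuli_per_subcategory = as.integer(n_stimuli_per_subcategory),
    seed = as.integer(seed)
  )
  structure(spec, class = "design_spec")
}

# exact per-cell counts; error names the first non-integral cell
design_cell_counts <- function(spec) {
  n <- spec$trials_per_category
  if (n %% 2L != 0L) {
    rlang::abort("trials_per_category must be even so the two cue levels are equiprobable")
  }
  n_cue <- n / 2
  counts <- c(
    Exp_Rep   = n_cue * spec$p_rep_given_highcue,
    Unexp_Alt = n_cue * (1 - spec$p_rep_given_highcue),
    Unexp_Rep = n_cue * spec$p_rep_given_lowcue,
    Exp_Alt   = n_cue * (1 - spec$p_rep_given_lowcue)
  )
  bad <- abs(counts - round(counts)) > 1e-9
  if (any(bad)) {
    rlang::abort(sprintf(
      "cell %s would contain %.2f trials; choose counts/probabilities giving whole trials per cell",
      names(counts)[bad][1], counts[bad][1]
    ))
  }
  as.integer(round(counts)) |> stats::setNames(names(counts))
}

# exact total target count via largest-remainder apportionment across cells
allocate_targets <- function(cell_counts, target_fraction) {
  total <- round(sum(cell_counts) * target_fraction)
  raw <- cell_counts * target_fraction
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_by_frac <- order(raw - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base) |> stats::setNames(names(cell_counts))
}

#' Build the trial table for one stimulus category
#'
#' Allocates the four expectation-by-repetition cells with exact counts,
#' marks target trials, randomizes the row order, and assigns stimulus
#' identities: S1 is drawn from the cue subcategory's pool avoiding reuse
#' within a sliding window of 4 trials; S2 equals S1 on repetition trials
#' and is a different exemplar otherwise.
#'
#' @param spec A [design_spec()].
#' @param category One of `spec$categories`.
#' @param alternation_pool Where alternation S2 exemplars come from:
#'   the whole `"category"` pool (default) or the cue `"subcategory"` pool.
#' @return A tibble with one row per trial: `trial_index`, `category`,
#'   `cue_level` (`high_rep`/`low_rep`), `s1_id`, `s2_id`, `is_repetition`,
#'   `is_expected`, `is_target`, `s1_size_reduced` (which pair member is
#'   rendered 18% smaller; bookkeeping only), `block`, `cell`.
#' @examples
#' trials <- build_category_trials(design_spec(), "word")
#' table(trials$cell)
#' @export
build_category_trials <- function(spec, category,
                                  alternation_pool = c("category", "subcategory")) {
  stopifnot(inherits(spec, "design_spec"))
  alternation_pool <- match.arg(alternation_pool)
  if (!category %in% spec$categories) {
    rlang::abort(sprintf("unknown category '%s'", category))
  }
  counts <- design_cell_counts(spec)
  targets <- allocate_targets(counts, spec$target_fraction)

  cells <- tibble::tibble(
    cell = names(counts),
    cue_level = c("high_rep", "high_rep", "low_rep", "low_rep"),
    is_repetition = c(TRUE, FALSE, TRUE, FALSE),
    n = as.integer(counts),
    n_target = targets[names(counts)]
  )
  rows <- purrr::pmap(cells, function(cell, cue_level, is_repetition, n, n_target) {
    tibble::tibble(
      category = category,
      cue_level = cue_level,
      is_repetition = is_repetition,
      is_target = rep(c(TRUE, FALSE), c(n_target, n - n_target))
    )
  })
  tab <- dplyr::bind_rows(rows)

  # seed offset by category rank so category tables differ but stay reproducible
  rng_seed <- spec$seed + match(category, spec$categories) - 1L
  tab <- withr_seed(rng_seed, {
    tab <- tab[sample.int(nrow(tab)), ]
    n_stim <- spec$n_stimuli_per_subcategory
    pools <- list(
      high_rep = sprintf("%s_high_%03d", category, seq_len(n_stim)),
      low_rep = sprintf("%s_low_%03d", category, seq_len(n_stim))
    )
    category_pool <- unlist(pools, use.names = FALSE)
    s1 <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      recent <- s1[max(1, i - 3):max(1, i - 1)]
      pool <- setdiff(pools[[tab$cue_level[i]]], recent)
      s1[i] <- pool[sample.int(length(pool), 1)]
    }
    s2 <- s1
    alt <- !tab$is_repetition
    for (i in which(alt)) {
      pool <- if (alternation_pool == "category") category_pool else pools[[tab$cue_level[i]]]
      pool <- setdiff(pool, s1[i])
      s2[i] <- pool[sample.int(length(pool), 1)]
    }
    tab$s1_id <- s1
    tab$s2_id <- s2
    tab$s1_size_reduced <- sample(c(TRUE, FALSE), nrow(tab), replace = TRUE)
    tab
  })

  tab$trial_index <- seq_len(nrow(tab))
  tab$is_expected <- (tab$cue_level == "high_rep") == tab$is_repetition
  tab$block <- 1L
  tab$cell <- condition_of(tab)
  tab[, c("trial_index", "category", "cue_level", "s1_id", "s2_id",
          "is_repetition", "is_expected", "is_target", "s1_size_reduced",
          "block", "cell")]
}

# evaluate expr with a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Condition cell of each trial
#'
#' Maps cue level and repetition status to the four design cells:
#' `Exp_Rep` (high-repetition cue, repeated), `Exp_Alt` (low cue,
#' alternated), `Unexp_Rep` (low cue, repeated), `Unexp_Alt` (high cue,
#' alternated).
#'
#' @param trials A trial table (or any data frame with `cue_level` and
#'   `is_repetition` columns).
#' @return Character vector of cell labels, one per row.
#' @export
condition_of <- function(trials) {
  cue <- trials$cue_level
  rep <- trials$is_repetition
  bad <- !cue %in% c("high_rep", "low_rep")
  if (any(bad)) {
    rlang::abort(sprintf("unknown cue level '%s'", cue[bad][1]))
  }
  expected <- (cue == "high_rep") == rep
  paste0(ifelse(expected, "Exp_", "Unexp_"), ifelse(rep, "Rep", "Alt"))
}

#' Build the full multi-category design
#'
#' Concatenates per-category trial tables in homogeneous blocks. Block
#' order is a seeded permutation of the categories (the counterbalancing
#' index), recorded in the `block_order` attribute.
#'
#' @inheritParams build_category_trials
#' @param block_order Optional explicit category order; defaults to a
#'   permutation drawn from `spec$seed`.
#' @return A tibble of `length(spec$categories) * spec$trials_per_category`
#'   trials with global `trial_index` and per-block `block` number.
#' @examples
#' nrow(build_full_design(design_spec())) # 1440
#' @export
build_full_design <- function(spec, block_order = NULL,
                              alternation_pool = c("category", "subcategory")) {
  stopifnot(inherits(spec, "design_spec"))
  alternation_pool <- match.arg(alternation_pool)
  if (is.null(block_order)) {
    block_order <- withr_seed(spec$seed, sample(spec$categories))
  }
  stopifnot(setequal(block_order, spec$categories))
  blocks <- purrr::imap(block_order, function(cat, b) {
    tab <- build_category_trials(spec, cat, alternation_pool)
    tab$block <- as.integer(b)
    tab
  })
  out <- dplyr::bind_rows(blocks)
  out$trial_index <- seq_len(nrow(out))
  attr(out, "block_order") <- block_order
  out
}

#' Read/write trial tables as CSV
#'
#' @param trials A trial table tibble.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial_index = readr::col_integer(),
                    block = readr::col_integer(),
                    is_repetition = readr::col_logical(),
                    is_expected = readr::col_logical(),
                    is_target = readr::col_logical(),
                    s1_size_reduced = readr::col_logical(),
                    .default = readr::col_character()
                  ))
}
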