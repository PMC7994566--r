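#' Synthetic cohort configuration
#'
#' Describes a cohort with the statistical structure the analysis
#' assumes: five correlated latent abilities (flexibility, working
#' memory, inhibition, attention, speed) drive both fluency behaviour
#' (cluster-structured word retrieval, latency profiles, error hazards)
#' and noisy executive-function scores, with demographic confounding.
#' Defaults emulate the study cohort: 230 participants aged 20-55
#' (mean 35.2, sd 11.1), 40% male, education distributed
#' 8/63/69/90 over the four ordinal levels.
#'
#' Three scenarios are available. `"realistic"` switches on all
#' couplings, including negative age slopes on the abilities.
#' `"null"` zeroes every loading, hazard coupling and confound effect,
#' so executive-function scores are pure noise and no feature-target
#' association exists by construction. `"planted"` routes signal
#' exclusively through semantic cohesion (working memory -> within-
#' cluster continuation) and latency slope (flexibility -> time-on-task
#' slowing) into one designated target, while word counts are driven by
#' the independent speed ability only — so the planted target is
#' predictable from the comprehensive feature set but carries no signal
#' reachable through sum scores.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param scenario One of `"realistic"`, `"null"`, `"planted"`.
#' @param planted_target EF variable carrying the planted signal
#'   (planted scenario).
#' @param ability_cor Latent ability correlation (realistic).
#' @param base_pause Mean inter-word pause in seconds at average speed.
#' @param slowing Time-on-task log-slope of pauses over the task.
#' @param overrides Named list overriding any internal parameter.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 230, seed = 1,
                          scenario = c("realistic", "null", "planted"),
                          planted_target = "spm_correct",
                          ability_cor = 0.3,
                          base_pause = 3.0,
                          slowing = 0.5,
                          overrides = list()) {
  scenario <- match.arg(scenario)
  on <- scenario == "realistic"
  pl <- scenario == "planted"
  par <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    scenario = scenario,
    planted_target = planted_target,
    duration = 120,
    abilities = c("flexibility", "working_memory", "inhibition", "attention", "speed"),
    ability_cor = if (on) ability_cor else 0,
    # demographics (study cohort margins)
    age_mean = 35.2, age_sd = 11.1, age_range = c(20, 55),
    p_male = 92 / 230,
    education_probs = c(8, 63, 69, 90) / 230,
    # confound effects on abilities (per SD age / per education step / male offset)
    beta_age = if (on) -0.35 else 0,
    beta_edu = if (on) 0.15 else 0,
    beta_sex = if (on) 0.10 else 0,
    # production model
    word_dur_meanlog = log(0.55), word_dur_sdlog = 0.15,
    base_pause = base_pause,
    task_pause_factor = c(t1 = 1.0, t2 = 1.1, t3 = 1.3),
    pause_sdlog = 0.35,
    # theta_speed lowers the mean pause; in the planted scenario it is the
    # *only* driver of word counts, keeping sum scores orthogonal to the
    # planted abilities; the null scenario zeroes it with everything else
    speed_pause = if (on || pl) 0.25 else 0,
    age_pause = if (on) 0.08 else 0,
    slowing = slowing,
    tilt_flex = if (pl) -0.35 else if (on) -0.10 else 0,  # flexibility flattens slowing
    stay_base = 0.9,
    stay_wm = if (on || pl) 0.7 else 0,   # working memory raises continuation prob
    switch_pen_base = if (on) 0.4 else 0, # extra pause on cluster switches
    switch_pen_flex = if (on) 0.15 else 0,
    rep_base = -3.2,
    rep_inh = if (on) -0.4 else 0,
    rep_wm = if (on) -0.25 else 0,
    cat_base = -3.5,
    cat_flex = if (on) -0.5 else 0,
    comply_base = 1.7,
    comply_flex = if (on) 0.5 else 0,
    # EF score model
    load_main_domain = if (on) 0.55 else 0,
    load_main_speed = if (on) 0.25 else 0,
    load_speed_domain = if (on) 0.15 else 0,
    load_speed_speed = if (on) 0.65 else 0,
    planted_w_wm = if (pl) 0.6 else 0,
    planted_w_flex = if (pl) 0.4 else 0,
    score_location = 50, score_scale = 10
  )
  par[names(overrides)] <- overrides
  structure(par, class = "cohort_config")
}

#' Ground truth planted by a generator configuration
#'
#' Returns the exact couplings the scenario plants — which mechanisms
#' carry signal into which targets and in which direction — for use by
#' recovery tests. The null scenario has an empty coupling set.
#'
#' @param config A [cohort_config()].
#' @return A list with `scenario`, `couplings` (tibble), `age_slope`.
#' @export
describe_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  couplings <- switch(config$scenario,
    null = tibble(target = character(), ability = character(),
                  pathway = character(), weight = numeric()),
    planted = tibble(
      target = config$planted_target,
      ability = c("working_memory", "flexibility"),
      pathway = c("semantic_cohesion", "latency_slope"),
      weight = c(config$planted_w_wm, config$planted_w_flex)),
    realistic = tibble(
      target = "all",
      ability = config$abilities,
      pathway = "domain_loading",
      weight = config$load_main_domain)
  )
  list(scenario = config$scenario, couplings = couplings,
       age_slope = config$beta_age)
}

# taxonomy category ids keyed by task category label
.label_to_cat <- c(animals = "animal", jobs = "occupation",
                   sports = "sport", fruits = "fruit")

# word pools per category: list(cat -> list(subtree -> words)), parsed from
# the toy taxonomy's dotted synset ids
.word_pools <- function(taxonomy) {
  lex <- taxonomy$lexicon
  parts <- strsplit(lex$synset_id, ".", fixed = TRUE)
  keep <- lengths(parts) == 3L
  df <- data.frame(cat = vapply(parts[keep], `[[`, "", 1L),
                   subtree = vapply(parts[keep], `[[`, "", 2L),
                   word = lex$word[keep])
  lapply(split(df, df$cat), function(d) split(d$word, d$subtree))
}

# simulate one session; returns a token tibble
.simulate_session <- function(task, theta, z_age, cfg, pools, rng_state = NULL) {
  dur <- cfg$duration
  labels <- .task_categories[[task]]
  # per-participant rates
  mu_pause <- cfg$base_pause * unname(cfg$task_pause_factor[task]) *
    exp(-cfg$speed_pause * theta[["speed"]] + cfg$age_pause * z_age)
  slow <- cfg$slowing + cfg$tilt_flex * theta[["flexibility"]]
  p_stay <- stats::plogis(cfg$stay_base + cfg$stay_wm * theta[["working_memory"]])
  pen <- max(0, cfg$switch_pen_base - cfg$switch_pen_flex * theta[["flexibility"]])
  p_rep <- stats::plogis(cfg$rep_base + cfg$rep_inh * theta[["inhibition"]] +
                           cfg$rep_wm * theta[["working_memory"]])
  p_cat <- if (task == "t3")
    stats::plogis(cfg$cat_base + cfg$cat_flex * theta[["flexibility"]]) else 0
  p_comply <- stats::plogis(cfg$comply_base + cfg$comply_flex * theta[["flexibility"]])

  # available words: label -> subtree -> unused words
  avail <- lapply(labels, function(lb) lapply(pools[[.label_to_cat[[lb]]]], sample))
  names(avail) <- labels
  cur_subtree <- stats::setNames(rep(NA_character_, length(labels)), labels)
  cur_label <- labels[1]

  word <- code <- category <- character(0)
  onset <- offset <- numeric(0)
  produced <- character(0)
  t_now <- stats::runif(1, 0.5, 2.5)
  switched <- FALSE
  repeat {
    w_dur <- stats::rlnorm(1, cfg$word_dur_meanlog, cfg$word_dur_sdlog)
    if (t_now + w_dur > dur) break
    kind <- "correct"
    if (length(produced) >= 3 && stats::runif(1) < p_rep) kind <- "repetition"
    else if (task == "t3" && stats::runif(1) < p_cat) kind <- "category"
    if (kind == "repetition") {
      w <- sample(produced, 1)
      lb <- cur_label
      cd <- "repetition_error"
    } else if (kind == "category") {
      wrong <- sample(setdiff(names(.label_to_cat), .task_categories[[task]]), 1)
      task_words <- unlist(pools[.label_to_cat[.task_categories[[task]]]],
                           use.names = FALSE)
      # dual-sense words that also belong to a task category are not errors
      pool <- setdiff(unlist(pools[[.label_to_cat[[wrong]]]], use.names = FALSE),
                      task_words)
      w <- sample(pool, 1)
      lb <- if (task == "t3") {
        if (length(category)) setdiff(labels, category[length(category)])[1] else labels[1]
      } else labels[1]
      cd <- "category_error"
    } else {
      # pick producing label: t3 alternates (lapses stay, coded correct)
      if (task == "t3" && length(category) > 0) {
        last_correct <- category[length(category)]
        lb <- if (stats::runif(1) < p_comply) setdiff(labels, last_correct)[1]
              else last_correct
      } else lb <- labels[1]
      sub <- avail[[lb]]
      n_left <- vapply(sub, length, integer(1))
      if (all(n_left == 0)) break  # category pool exhausted
      cs <- cur_subtree[[lb]]
      stay_ok <- !is.na(cs) && n_left[[cs]] > 0
      if (stay_ok && stats::runif(1) < p_stay) {
        st <- cs; switched <- FALSE
      } else {
        candidates <- names(n_left)[n_left > 0]
        if (!is.na(cs)) candidates <- setdiff(candidates, cs)
        if (length(candidates) == 0) candidates <- names(n_left)[n_left > 0]
        st <- if (length(candidates) == 1) candidates else sample(candidates, 1)
        switched <- !is.na(cs)
      }
      w <- avail[[lb]][[st]][1]
      avail[[lb]][[st]] <- avail[[lb]][[st]][-1]
      cur_subtree[[lb]] <- st
      cur_label <- lb
      cd <- "correct"
      produced <- c(produced, w)
    }
    word <- c(word, w); code <- c(code, cd)
    category <- c(category, if (task == "t3") lb else NA_character_)
    onset <- c(onset, t_now); offset <- c(offset, t_now + w_dur)
    # pause to the next word, assigned at the current offset
    frac <- (t_now + w_dur) / dur
    pause <- mu_pause * exp(slow * (frac - 0.5)) *
      (if (switched && cd == "correct") exp(pen) else 1) *
      stats::rlnorm(1, -cfg$pause_sdlog^2 / 2, cfg$pause_sdlog)
    t_now <- t_now + w_dur + pause
  }
  cat_col <- if (task == "t3") category else rep(NA_character_, length(word))
  tibble(task = rep(task, length(word)), word = word, onset = onset,
         offset = offset, code = code, category = cat_col)
}

#' Generate a synthetic cohort
#'
#' Draws demographics, latent abilities (confounded by age, sex and
#' education per scenario), simulates one fluency session per task as a
#' cluster-structured walk over the bundled toy taxonomy's category
#' subtrees (stay within the current subtree with the
#' continuation probability, otherwise jump; sampling without
#' replacement so exhausting a subtree forces a switch), with lognormal
#' latencies carrying a time-on-task slope and cluster-switch penalty,
#' injected repetition and category errors, and finally builds the
#' 68-variable executive-function score table as noisy linear
#' combinations of the abilities per the registry's domain and polarity.
#'
#' @param config A [cohort_config()].
#' @param taxonomy Word-pool taxonomy (default: the bundled toy
#'   resource).
#' @return A list with `sessions` (validated token tibble),
#'   `demographics`, `ef_scores` (schema attached), `abilities` (latent
#'   truth), and `truth` ([describe_truth()]).
#' @export
generate_cohort <- function(config = cohort_config(), taxonomy = toy_taxonomy()) {
  stopifnot(inherits(config, "cohort_config"))
  schema <- ef_schema()
  pools <- .word_pools(taxonomy)
  withr::with_seed(config$seed, {
    n <- config$n_participants
    ids <- sprintf("p%03d", seq_len(n))
    age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                     config$age_range[1]), config$age_range[2])
    sex <- stats::rbinom(n, 1, config$p_male)
    education <- sample(1:4, n, replace = TRUE, prob = config$education_probs)
    demographics <- tibble(participant_id = ids, sex = sex, age = age,
                           education = education)
    z_age <- (age - config$age_mean) / config$age_sd

    k <- length(config$abilities)
    R <- matrix(config$ability_cor, k, k); diag(R) <- 1
    z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
    theta <- z +
      config$beta_age * z_age +
      config$beta_edu * (education - mean(1:4)) +
      config$beta_sex * (sex - 0.5)
    colnames(theta) <- config$abilities

    sessions <- purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(c("t1", "t2", "t3"), function(tk) {
        mutate(.simulate_session(tk, theta[i, ], z_age[i], config, pools),
               participant_id = ids[i])
      })
    })
    sessions <- validate_sessions(
      select(sessions, all_of(c("participant_id", "task", "word",
                                "onset", "offset", "code", "category"))),
      duration = config$duration)

    domain_ability <- c(cognitive_flexibility = "flexibility",
                        working_memory = "working_memory",
                        inhibition = "inhibition",
                        attention = "attention",
                        vigilance = "attention")
    ef <- matrix(NA_real_, n, nrow(schema),
                 dimnames = list(NULL, schema$variable))
    for (j in seq_len(nrow(schema))) {
      v <- schema$variable[j]
      if (config$scenario == "planted" && v == config$planted_target) {
        lam2 <- config$planted_w_wm^2 + config$planted_w_flex^2
        latent <- config$planted_w_wm * theta[, "working_memory"] +
          config$planted_w_flex * theta[, "flexibility"]
      } else {
        ld <- if (schema$kind[j] == "speed") config$load_speed_domain else config$load_main_domain
        ls <- if (schema$kind[j] == "speed") config$load_speed_speed else config$load_main_speed
        lam2 <- ld^2 + ls^2
        latent <- ld * theta[, domain_ability[[schema$domain[j]]]] +
          ls * theta[, "speed"]
      }
      noise_sd <- sqrt(max(0.15, 1 - lam2))
      raw <- latent + stats::rnorm(n, sd = noise_sd)
      sign <- if (schema$polarity[j] == "lower_better") -1 else 1
      ef[, j] <- config$score_location + config$score_scale * sign * raw
    }
    ef_scores <- dplyr::bind_cols(tibble(participant_id = ids), as_tibble(ef))
    attr(ef_scores, "schema") <- schema
    list(sessions = sessions, demographics = demographics,
         ef_scores = ef_scores,
         abilities = dplyr::bind_cols(tibble(participant_id = ids), as_tibble(theta)),
         truth = describe_truth(config))
  })
}
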