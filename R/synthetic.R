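#' Synthetic study configuration
#'
#' Defines the conditions of the emulated study: 17 MDD and 14 control
#' subjects, 1056 volumes at TR = 2 s (96 trials of 22 s), an infra-slow
#' (0.01-0.1 Hz) shared global component with group-dependent regional
#' loadings, and 4-level severity responses drawn from a known
#' multinomial-logit model.
#'
#' Each subject's voxel series is `lambda_region * g(t) + sqrt(1 -
#' lambda_region^2) * h_region(t) + noise`, where `g` is the subject's shared
#' band-limited global component, `h_region` an independent band-limited
#' innovation of the region containing the voxel, and `lambda_region` the
#' subject's loading, drawn from a group-specific mean with between-subject
#' spread `loading_sd`. Defaults are calibrated so that layer GSCORR
#' reproduces the reported group profile: near-zero exteroceptive/mental
#' Fisher-z values in controls versus about 0.3 (exteroceptive) and 0.25
#' (mental) in the MDD arm, with between-subject SD about 0.2.
#'
#' @param n_mdd,n_ctrl Group sizes.
#' @param n_trials Trials per subject (22 s each).
#' @param n_reappraise_neg,n_attend_neg Negative-reappraise and
#'   negative-attend trial counts; the remainder are neutral-attend.
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes per run; must equal `22 * n_trials / tr`.
#' @param voxel_size Isotropic voxel size in mm of the simulation grid.
#' @param layers Self-layer definitions ([default_self_layers()]).
#' @param layer_loadings Named list, one `c(ctrl=, mdd=)` pair per layer:
#'   group-mean loadings of the shared global component.
#' @param background_loading Loading of non-layer gray matter (drives the
#'   global signal).
#' @param loading_sd Between-subject SD of the layer loadings.
#' @param gs_band Pass band (Hz) of the shared component.
#' @param noise_sd SD of white voxel noise, in units of the (unit-variance)
#'   shared component.
#' @param behavior_coefs Named list of [behavior_coefs()] matrices per
#'   condition (`negative_attend`, `negative_reappraise`, `neutral_attend`).
#' @param p_missing Probability that a trial receives no button press.
#' @param n_always_press Number of subjects (taken from the end of the MDD
#'   arm) that press in every 2-s rating window of every trial, emulating the
#'   excluded always-pressing participant.
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mdd = 17L, n_ctrl = 14L,
                             n_trials = 96L,
                             n_reappraise_neg = 30L, n_attend_neg = 18L,
                             tr = 2, n_volumes = NULL,
                             voxel_size = 6,
                             layers = default_self_layers(),
                             layer_loadings = list(
                               interoceptive = c(ctrl = 0.03, mdd = 0.08),
                               exteroceptive = c(ctrl = 0.00, mdd = 0.34),
                               mental        = c(ctrl = 0.02, mdd = 0.28)
                             ),
                             background_loading = 0.9,
                             loading_sd = 0.22,
                             gs_band = c(0.01, 0.1),
                             noise_sd = 1,
                             behavior_coefs = default_behavior_coefs(),
                             p_missing = 0.02,
                             n_always_press = 1L,
                             seed = 1L) {
  if (any(c(n_mdd, n_ctrl, n_trials) <= 0)) stop("counts must be positive")
  schedule_volumes <- as.integer(round(22 * n_trials / tr))
  if (is.null(n_volumes)) n_volumes <- schedule_volumes
  if (n_volumes != schedule_volumes)
    stop("n_volumes (", n_volumes, ") must match the task schedule duration: ",
         "22 s x ", n_trials, " trials / TR ", tr, " s = ", schedule_volumes)
  if (!setequal(names(layer_loadings),
                vapply(layers, `[[`, character(1), "layer")))
    stop("`layer_loadings` names must match the layer names")
  lam <- c(unlist(layer_loadings), background_loading, loading_sd)
  if (any(!is.finite(lam))) stop("loadings must be finite")
  geom <- simulation_grid(layers, voxel_size)
  structure(list(
    n_mdd = as.integer(n_mdd), n_ctrl = as.integer(n_ctrl),
    n_trials = as.integer(n_trials),
    n_reappraise_neg = as.integer(n_reappraise_neg),
    n_attend_neg = as.integer(n_attend_neg),
    tr = tr, n_volumes = as.integer(n_volumes),
    voxel_size = voxel_size, grid_dim = geom$grid_dim, affine = geom$affine,
    layers = layers, layer_loadings = layer_loadings,
    background_loading = background_loading, loading_sd = loading_sd,
    gs_band = gs_band, noise_sd = noise_sd,
    behavior_coefs = behavior_coefs,
    p_missing = p_missing, n_always_press = as.integer(n_always_press),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulation grid covering a set of layers
#'
#' Builds an isotropic grid whose bounding box covers every sphere centre plus
#' its radius and one voxel of margin.
#'
#' @param layers List of [layer_definition()]s.
#' @param voxel_size Voxel size in mm.
#' @return List with `grid_dim` (3 counts) and `affine` (4x4).
#' @export
simulation_grid <- function(layers, voxel_size) {
  centers <- do.call(rbind, lapply(layers, function(l)
    do.call(rbind, lapply(l$rois, function(r) r$center))))
  radius <- max(unlist(lapply(layers, function(l)
    vapply(l$rois, `[[`, numeric(1), "radius"))))
  lo <- apply(centers, 2, min) - radius - voxel_size
  hi <- apply(centers, 2, max) + radius + voxel_size
  n <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  list(grid_dim = n, affine = affine)
}

region_masks <- function(config) {
  masks <- assert_disjoint_layers(config$layers, config$grid_dim,
                                  config$affine)
  background <- !Reduce(`|`, masks)
  c(list(background = background), masks)
}

region_voxel_counts <- function(config) {
  vapply(region_masks(config), sum, numeric(1))
}

group_lambda_means <- function(config, subject_group) {
  lay <- vapply(config$layer_loadings, `[[`, numeric(1),
                if (subject_group == "mdd") "mdd" else "ctrl")
  c(background = config$background_loading, lay)
}

draw_subject_loadings <- function(config, subject_group) {
  mu <- group_lambda_means(config, subject_group)
  lam <- mu
  lay <- setdiff(names(mu), "background")
  lam[lay] <- rnorm(length(lay), mu[lay], config$loading_sd)
  pmin(pmax(lam, -1), 1)
}

# Band-limited, in-sample orthonormal basis: each column is white noise
# band-passed to `band`, then jointly demeaned, Gram-Schmidt orthogonalised
# and scaled to sample SD 1. Columns are deterministic up to sign, which is
# fixed so that the construction is reproducible.
orthonormal_band_series <- function(n_t, tr, band, n_series) {
  spec <- filter_spec(band[1], band[2], tr)
  raw <- matrix(rnorm(n_t * n_series), n_t, n_series)
  f <- temporal_filter(raw, spec)
  f <- sweep(f, 2, colMeans(f))
  qd <- qr(f)
  Q <- qr.Q(qd)
  sgn <- sign(diag(qr.R(qd)))
  sgn[sgn == 0] <- 1
  Q <- sweep(Q, 2, sgn, `*`)
  Q * sqrt(n_t - 1)
}

#' Analytic layer GSCORR implied by loadings
#'
#' Closed-form Pearson correlation between each region's mean series and the
#' global signal under the generative model, given the regional loadings and
#' voxel counts. With `noise_sd = 0` and the in-sample orthonormal
#' construction used by [generate_bold()], the pipeline estimate equals this
#' value to numerical precision; with noise it is the population value.
#'
#' @param lambda Named loading vector (background + layers).
#' @param m Named voxel counts, same names.
#' @param noise_sd Voxel noise SD.
#' @return A tibble with columns `region`, `rho`, `z`.
#' @export
analytic_layer_gscorr <- function(lambda, m, noise_sd = 0) {
  stopifnot(setequal(names(lambda), names(m)))
  m <- m[names(lambda)]
  v <- sum(m)
  alpha <- sum(m * lambda) / v
  beta <- m * sqrt(pmax(0, 1 - lambda^2)) / v
  var_gs <- alpha^2 + sum(beta^2) + noise_sd^2 / v
  cov_r <- lambda * alpha + sqrt(pmax(0, 1 - lambda^2)) * beta
  var_r <- 1 + noise_sd^2 / m
  rho <- as.numeric(cov_r / sqrt(var_r * var_gs))
  tibble::tibble(region = names(lambda), rho = rho,
                 z = atanh(pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)))
}

#' Generate a task schedule
#'
#' Builds `n_trials` trials of 22 s each (4 s view, 4 s attend/reappraise,
#' 4 s blank, four 2-s rating windows, 2 s relax) in randomized order:
#' `n_reappraise_neg` negative-reappraise, `n_attend_neg` negative-attend,
#' remainder neutral-attend.
#'
#' @param n_trials Total trials.
#' @param n_reappraise_neg Negative trials with the reappraise instruction.
#' @param n_attend_neg Negative trials with the attend instruction.
#' @param seed Integer seed for the trial-order shuffle.
#' @return A tibble with columns `trial`, `onset`, `duration`, `valence`,
#'   `instruction`, `rating_onset`, `rating_end` (seconds).
#' @export
generate_task_schedule <- function(n_trials = 96L, n_reappraise_neg = 30L,
                                   n_attend_neg = 18L, seed = 1L) {
  if (any(c(n_trials, n_reappraise_neg, n_attend_neg) < 0))
    stop("trial counts must be non-negative")
  if (n_reappraise_neg + n_attend_neg > n_trials)
    stop("negative trial counts exceed `n_trials`")
  n_neutral <- n_trials - n_reappraise_neg - n_attend_neg
  valence <- c(rep("negative", n_reappraise_neg + n_attend_neg),
               rep("neutral", n_neutral))
  instruction <- c(rep("reappraise", n_reappraise_neg),
                   rep("attend", n_attend_neg + n_neutral))
  ord <- withr::with_seed(seed, sample.int(n_trials))
  onset <- (seq_len(n_trials) - 1) * 22
  tibble::tibble(
    trial = seq_len(n_trials), onset = onset, duration = 22,
    valence = valence[ord], instruction = instruction[ord],
    rating_onset = onset + 12, rating_end = onset + 20
  )
}

#' Generate one subject's synthetic BOLD dataset
#'
#' See [synthetic_config()] for the generative model. The global component
#' and the regional innovations are orthonormal in-sample, so with
#' `noise_sd = 0` the pipeline GSCORR equals [analytic_layer_gscorr()]
#' exactly. The subject's drawn loadings and implied layer GSCORR are
#' attached as attribute `"truth"`.
#'
#' @param config A [synthetic_config()].
#' @param subject_group `"mdd"` or `"ctrl"`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [bold_dataset()].
#' @export
generate_bold <- function(config, subject_group = c("mdd", "ctrl"),
                          seed = config$seed) {
  subject_group <- match.arg(subject_group)
  masks <- region_masks(config)
  m <- vapply(masks, sum, numeric(1))
  n_t <- config$n_volumes
  region_index <- as.vector(
    Reduce(`+`, Map(function(msk, i) i * msk, masks, seq_along(masks))))
  out <- withr::with_seed(seed, {
    lambda <- draw_subject_loadings(config, subject_group)
    S <- orthonormal_band_series(n_t, config$tr, config$gs_band,
                                 1L + length(masks))
    g <- S[, 1]
    region_series <- vapply(seq_along(masks), function(r) {
      lambda[r] * g + sqrt(max(0, 1 - lambda[r]^2)) * S[, 1 + r]
    }, numeric(n_t))
    M <- t(region_series)[region_index, , drop = FALSE]
    if (config$noise_sd > 0)
      M <- M + config$noise_sd * matrix(rnorm(length(M)), nrow(M))
    list(M = M, lambda = lambda)
  })
  bold <- bold_dataset(array(out$M, c(config$grid_dim, n_t)),
                       config$affine, config$tr)
  attr(bold, "truth") <- list(
    group = subject_group, lambda = out$lambda, m = m,
    gscorr = analytic_layer_gscorr(out$lambda, m, config$noise_sd)
  )
  bold
}

softmax_probs <- function(coefs, x) {
  reference <- attr(coefs, "reference")
  categories <- attr(coefs, "categories")
  eta <- as.numeric(coefs %*% x)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  full <- setNames(numeric(length(categories)), categories)
  full[rownames(coefs)] <- eta
  p <- exp(full - max(full))
  p / sum(p)
}

#' Multinomial-logit coefficient matrix for the behavioural simulator
#'
#' @param mat Numeric matrix, one row per non-reference severity category (in
#'   category order), columns `(Intercept)`, `interoceptive`,
#'   `exteroceptive`, `mental`, `group`.
#' @param reference Reference severity category (character).
#' @param categories All severity categories, in order.
#' @return The matrix with `reference`/`categories` attributes.
#' @export
behavior_coefs <- function(mat, reference,
                           categories = c("1", "2", "3", "4")) {
  mat <- as.matrix(mat)
  if (!reference %in% categories) stop("`reference` not among `categories`")
  non_ref <- setdiff(categories, reference)
  if (nrow(mat) != length(non_ref))
    stop("need one coefficient row per non-reference category")
  rownames(mat) <- non_ref
  colnames(mat) <- c("(Intercept)", "interoceptive", "exteroceptive",
                     "mental", "group")
  attr(mat, "reference") <- reference
  attr(mat, "categories") <- categories
  mat
}

#' Default behavioural coefficient matrices
#'
#' Per-condition ground-truth multinomial-logit coefficients for the
#' simulator. Slopes come from the published per-condition models (see
#' [published_mlr_coefficients()]); intercepts, which were not published, are
#' fixed so that the reference category (mild for negative, weak for neutral
#' stimuli) is the modal response, matching the stated rationale for its
#' choice as reference.
#'
#' @return Named list of three [behavior_coefs()] matrices.
#' @export
default_behavior_coefs <- function() {
  list(
    negative_attend = behavior_coefs(rbind(
      c(-0.6, 8.397, 0, -2.851, 0),      # weak  vs mild
      c(-0.4, 2.032, -1.418, 0, 1.043),  # moderate vs mild
      c(-1.2, 0, 0, 0, 1.683)            # strong vs mild
    ), reference = "2"),
    negative_reappraise = behavior_coefs(rbind(
      c(-0.3, 4.378, 2.209, 0, -1.396),
      c(-0.5, 0, -1.037, 0, 0.78),
      c(-1.4, 2.778, -4.432, 0, 1.46)
    ), reference = "2"),
    neutral_attend = behavior_coefs(rbind(
      c(-0.5, 0, -2.849, 1.675, 0.58),   # mild vs weak
      c(-1.2, 0, -2.02, 0, 1.721),       # moderate vs weak
      c(-2.0, 0, 0, 0, 2.097)            # strong vs weak
    ), reference = "1")
  )
}

#' Sample severity responses from a known multinomial model
#'
#' Draws `n_trials` 4-level severity responses from the softmax probabilities
#' implied by `true_coefs` applied to the subject's layer GSCORR values and
#' group indicator.
#'
#' @param gscorr_row Named numeric vector with elements `interoceptive`,
#'   `exteroceptive`, `mental` (Fisher-z values).
#' @param group `"mdd"` or `"ctrl"`.
#' @param true_coefs A [behavior_coefs()] matrix.
#' @param n_trials Number of responses to draw.
#' @param seed Integer seed.
#' @return Integer vector of severities in 1..4.
#' @export
generate_behavior <- function(gscorr_row, group, true_coefs, n_trials,
                              seed = 1L) {
  x <- c(1, gscorr_row[c("interoceptive", "exteroceptive", "mental")],
         as.numeric(group == "mdd"))
  p <- softmax_probs(true_coefs, x)
  categories <- as.integer(attr(true_coefs, "categories"))
  withr::with_seed(seed,
    sample(categories, n_trials, replace = TRUE, prob = p))
}

subject_seed <- function(seed, i, k = 0L) {
  as.integer((as.numeric(seed) + 104729 * i + 7919 * k) %% 2147483629)
}

#' Generate a full synthetic cohort
#'
#' Composes the BOLD, schedule and behaviour generators: a subject table
#' (group, synthetic HAMD with MDD > CTRL, matched age/education), one BOLD
#' dataset per subject, and a trial-level response table. Responses are
#' driven by each subject's model-implied ("true") layer GSCORR, so the
#' neural-behaviour link can be recovered downstream. The last
#' `n_always_press` MDD subjects press in every rating window of every trial
#' and are the targets of the behavioural exclusion rule.
#'
#' @param config A [synthetic_config()].
#' @param include_bold Set `FALSE` to skip building the (large) BOLD arrays;
#'   subject truth, schedules and behaviour are unchanged.
#' @return List with `subjects`, `trials`, `truth` (per-subject true layer
#'   Fisher-z values) and `bold` (named list of [bold_dataset()]s or `NULL`).
#' @export
generate_cohort <- function(config, include_bold = TRUE) {
  n <- config$n_mdd + config$n_ctrl
  ids <- sprintf("sub-%02d", seq_len(n))
  group <- rep(c("mdd", "ctrl"), c(config$n_mdd, config$n_ctrl))
  subjects <- withr::with_seed(config$seed, tibble::tibble(
    subject = ids, group = group,
    hamd = round(ifelse(group == "mdd", runif(n, 7, 17), runif(n, 0, 5)), 1),
    age = round(rnorm(n, 48, 5), 1),
    education = round(pmax(rnorm(n, 8, 3.5), 2))
  ))
  always_press <- rep(FALSE, n)
  if (config$n_always_press > 0) {
    idx <- seq(config$n_mdd - config$n_always_press + 1L, config$n_mdd)
    always_press[idx] <- TRUE
  }
  m <- region_voxel_counts(config)
  bold <- if (include_bold) vector("list", n) else NULL
  truth_rows <- vector("list", n)
  trial_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- subject_seed(config$seed, i)
    if (include_bold) {
      b <- generate_bold(config, group[i], seed = s_i)
      tr_i <- attr(b, "truth")
      bold[[i]] <- b
    } else {
      lambda <- withr::with_seed(s_i,
        draw_subject_loadings(config, group[i]))
      tr_i <- list(group = group[i], lambda = lambda, m = m,
                   gscorr = analytic_layer_gscorr(lambda, m, config$noise_sd))
    }
    z <- setNames(tr_i$gscorr$z, tr_i$gscorr$region)
    truth_rows[[i]] <- tibble::tibble(
      subject = ids[i], group = group[i],
      layer = setdiff(names(z), "background"),
      z = as.numeric(z[setdiff(names(z), "background")])
    )
    sched <- generate_task_schedule(config$n_trials, config$n_reappraise_neg,
                                    config$n_attend_neg,
                                    seed = subject_seed(config$seed, i, 1L))
    cond <- paste(sched$valence, sched$instruction, sep = "_")
    resp <- integer(config$n_trials)
    for (cc in unique(cond)) {
      sel <- cond == cc
      resp[sel] <- generate_behavior(z, group[i], config$behavior_coefs[[cc]],
                                     sum(sel),
                                     seed = subject_seed(config$seed, i,
                                                         2L + match(cc, names(config$behavior_coefs))))
    }
    miss <- withr::with_seed(subject_seed(config$seed, i, 9L),
                             runif(config$n_trials) < config$p_missing)
    if (always_press[i]) {
      tw <- sched[rep(seq_len(config$n_trials), each = 4L), ]
      trial_rows[[i]] <- tibble::tibble(
        subject = ids[i], group = group[i], trial = tw$trial,
        onset = tw$onset, valence = tw$valence, instruction = tw$instruction,
        response = rep(1:4, config$n_trials),
        response_rank = rep(1:4, config$n_trials)
      )
    } else {
      trial_rows[[i]] <- tibble::tibble(
        subject = ids[i], group = group[i], trial = sched$trial,
        onset = sched$onset, valence = sched$valence,
        instruction = sched$instruction,
        response = ifelse(miss, NA_integer_, resp),
        response_rank = ifelse(miss, NA_integer_, 1L)
      )
    }
  }
  if (include_bold) names(bold) <- ids
  list(subjects = subjects,
       trials = do.call(rbind, trial_rows),
       truth = do.call(rbind, truth_rows),
       bold = bold)
}

#' Region-level fast path: simulated layer GSCORR for a cohort
#'
#' Simulates the measured per-subject layer Fisher-z GSCORR values without
#' building voxel arrays. Because every pipeline step (masked averaging,
#' volume discard, filtering, correlation with the voxel-mean global signal)
#' is linear in the voxel data, the distribution of the measured values
#' depends on the voxel field only through the region mean series and their
#' correctly correlated region-mean noise, which are simulated directly. Used
#' for seed-intensive power studies.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param n_discard Initial volumes to discard (default 2).
#' @param apply_filter Re-apply the infra-slow band-pass before correlating,
#'   as the voxelwise pipeline does.
#' @return A tibble with columns `subject`, `group`, `layer`, `rho`, `z`.
#' @export
simulate_layer_gscorr <- function(config, seed = config$seed,
                                  n_discard = 2L, apply_filter = TRUE) {
  m <- region_voxel_counts(config)
  v <- sum(m)
  n <- config$n_mdd + config$n_ctrl
  ids <- sprintf("sub-%02d", seq_len(n))
  group <- rep(c("mdd", "ctrl"), c(config$n_mdd, config$n_ctrl))
  n_t <- config$n_volumes
  spec <- filter_spec(config$gs_band[1], config$gs_band[2], config$tr)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- withr::with_seed(subject_seed(seed, i), {
      lambda <- draw_subject_loadings(config, group[i])
      S <- orthonormal_band_series(n_t, config$tr, config$gs_band,
                                   1L + length(m))
      g <- S[, 1]
      x <- vapply(seq_along(m), function(r) {
        lambda[r] * g + sqrt(max(0, 1 - lambda[r]^2)) * S[, 1 + r] +
          (config$noise_sd / sqrt(m[r])) * rnorm(n_t)
      }, numeric(n_t))
      x
    })
    gs <- as.numeric(sim %*% (m / v))
    keep <- (n_discard + 1L):n_t
    sim <- sim[keep, , drop = FALSE]
    gs <- gs[keep]
    if (apply_filter) {
      sim <- temporal_filter(sim, spec)
      gs <- temporal_filter(gs, spec)
    }
    layer_names <- setdiff(names(m), "background")
    g_list <- lapply(layer_names, function(nm) {
      gg <- compute_gscorr(sim[, match(nm, names(m))], gs)
      tibble::tibble(subject = ids[i], group = group[i], layer = nm,
                     rho = gg$rho, z = gg$z)
    })
    rows[[i]] <- do.call(rbind, g_list)
  }
  do.call(rbind, rows)
}
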