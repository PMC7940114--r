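#' Specification of a synthetic resting-state cohort
#'
#' Describes a two-group cohort of parcellated-like ROI time series with a
#' modular correlation structure and, optionally, planted node-level group
#' differences.  The generator emulates the regime of atlas-parcellated
#' resting-state fMRI: 84 ROIs, runs of about 150 volumes at a repetition
#' time of 2 s, and correlations organised into a small number of modules
#' (resting-state-network-like blocks).
#'
#' Each module `m` has one latent band-limited signal.  An ROI assigned to
#' module `m` is a weighted sum of its own-module latent
#' (`within_module_coupling`), one designated other-module latent
#' (`cross_module_coupling`, possibly applied at a lag of 1--3 samples),
#' and white Gaussian noise (`noise_sd`).  A fixed 15% of ROIs are
#' connector hubs whose cross-module coupling equals the within-module
#' value; they emulate the inter-network hub regions that keep empirical
#' k-NN graphs connected.  The ROIs named in `planted_nodes` carry the
#' planted group differences:
#' * `"raise_participation"` nodes start from an integrative-hub baseline
#'   (even coupling to their own and one partner module); in patients the
#'   node's coupling spreads into every remaining module with coefficient
#'   `effect_size`, rescaled so its total coupling energy is unchanged --
#'   the downstream participation coefficient rises while strength does
#'   not;
#' * `"lower_strength"` multiplies all the node's coupling coefficients by
#'   `1 - effect_size`, decorrelating it from the network and so lowering
#'   its downstream strength.
#'
#' Patients express every planted effect in full; 20% of controls are
#' subclinical carriers of one planted effect (severity drawn from
#' U(0.5, 0.75)), mirroring the single-marker overlap that limits the
#' specificity of individual biomarkers in real cohorts.  An
#' `effect_size` of `0.8` is the documented "strong" setting used by the
#' package's own recovery checks.
#'
#' @param n_controls,n_patients Number of subjects per group.
#' @param n_rois Number of ROIs (columns), default 84.
#' @param n_timepoints Number of samples per series (rows), default 150.
#' @param n_modules Number of latent modules, default 4.  ROIs are split
#'   into contiguous blocks of equal size; remainder ROIs join the last
#'   module.
#' @param within_module_coupling,cross_module_coupling Coupling
#'   coefficients in `[0, 1)`; either a single value shared by both groups
#'   or a length-2 vector `c(control, patient)`.
#' @param lag_fraction Fraction of ROIs whose cross-module coupling is
#'   applied at a lag drawn uniformly from `{1, 2, 3}` samples.
#' @param noise_sd Standard deviation of the additive white noise (> 0).
#' @param planted_nodes `NULL`, or a data frame with columns `roi_index`
#'   (1-based), `effect` (`"raise_participation"` or `"lower_strength"`)
#'   and `effect_size` (> 0); applied to patient subjects only.
#' @param master_seed Integer seed; the cohort is a pure function of the
#'   spec including this seed.
#' @param tr_seconds Repetition time stored on each subject, default 2.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [planted_truth()]
#' @export
synthetic_spec <- function(n_controls,
                           n_patients,
                           n_rois = 84L,
                           n_timepoints = 150L,
                           n_modules = 4L,
                           within_module_coupling = 0.8,
                           cross_module_coupling = 0.25,
                           lag_fraction = 0.25,
                           noise_sd = 0.6,
                           planted_nodes = NULL,
                           master_seed = 1L,
                           tr_seconds = 2) {
  chk_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
      abort_embedfcn(sprintf("field '%s' must be an integer >= %d", name, min),
                     "embedfcn_validation_error")
    as.integer(x)
  }
  chk_coupling <- function(x, name) {
    if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || anyNA(x) ||
        any(x < 0) || any(x >= 1))
      abort_embedfcn(sprintf("field '%s' must be 1 or 2 values in [0, 1)", name),
                     "embedfcn_validation_error")
    if (length(x) == 1L) rep(x, 2L) else as.numeric(x)
  }
  n_controls <- chk_count(n_controls, "n_controls", 0L)
  n_patients <- chk_count(n_patients, "n_patients", 0L)
  n_rois <- chk_count(n_rois, "n_rois")
  n_timepoints <- chk_count(n_timepoints, "n_timepoints", 8L)
  n_modules <- chk_count(n_modules, "n_modules")
  if (n_modules > n_rois)
    abort_embedfcn("field 'n_modules' must not exceed n_rois",
                   "embedfcn_validation_error")
  within_module_coupling <- chk_coupling(within_module_coupling, "within_module_coupling")
  cross_module_coupling <- chk_coupling(cross_module_coupling, "cross_module_coupling")
  if (!is.numeric(lag_fraction) || length(lag_fraction) != 1L ||
      is.na(lag_fraction) || lag_fraction < 0 || lag_fraction > 1)
    abort_embedfcn("field 'lag_fraction' must be a fraction in [0, 1]",
                   "embedfcn_validation_error")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd <= 0)
    abort_embedfcn("field 'noise_sd' must be > 0", "embedfcn_validation_error")
  if (!is.null(planted_nodes)) {
    if (!is.data.frame(planted_nodes) ||
        !all(c("roi_index", "effect", "effect_size") %in% names(planted_nodes)))
      abort_embedfcn(
        "field 'planted_nodes' must be a data frame with columns roi_index, effect, effect_size",
        "embedfcn_validation_error")
    if (any(planted_nodes$roi_index < 1) || any(planted_nodes$roi_index > n_rois))
      abort_embedfcn("field 'planted_nodes': every roi_index must be in 1..n_rois",
                     "embedfcn_validation_error")
    if (!all(planted_nodes$effect %in% c("raise_participation", "lower_strength")))
      abort_embedfcn(
        "field 'planted_nodes': effect must be 'raise_participation' or 'lower_strength'",
        "embedfcn_validation_error")
    if (any(planted_nodes$effect_size <= 0))
      abort_embedfcn("field 'planted_nodes': effect_size must be > 0",
                     "embedfcn_validation_error")
  }
  master_seed <- chk_count(master_seed, "master_seed", 0L)
  structure(
    list(
      n_controls = n_controls, n_patients = n_patients,
      n_rois = n_rois, n_timepoints = n_timepoints, n_modules = n_modules,
      within_module_coupling = within_module_coupling,
      cross_module_coupling = cross_module_coupling,
      lag_fraction = lag_fraction, noise_sd = noise_sd,
      planted_nodes = planted_nodes,
      master_seed = master_seed, tr_seconds = tr_seconds
    ),
    class = "synthetic_spec"
  )
}

#' One subject's parcellated ROI time series
#'
#' @param subject_id Character id.
#' @param label Class label, 0 = control, 1 = patient.
#' @param data Numeric T x M matrix (timepoints x ROIs) with column names.
#' @param tr_seconds Repetition time in seconds.
#'
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(subject_id, label, data, tr_seconds = 2) {
  data <- as.matrix(data)
  if (anyNA(data))
    abort_embedfcn(sprintf("subject '%s': time series contain missing values", subject_id),
                   "embedfcn_validation_error")
  if (!label %in% c(0L, 1L))
    abort_embedfcn(sprintf("subject '%s': label must be 0 or 1", subject_id),
                   "embedfcn_validation_error")
  v <- apply(data, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(data)[which(v == 0)[1L]] %||% which(v == 0)[1L]
    abort_embedfcn(sprintf("subject '%s': ROI '%s' has zero variance", subject_id, bad),
                   "embedfcn_degenerate_error")
  }
  if (is.null(colnames(data))) colnames(data) <- roi_labels(ncol(data))
  structure(list(subject_id = as.character(subject_id), label = as.integer(label),
                 data = data, tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' Default ROI label vector
#'
#' @param m Number of ROIs.
#' @return Character vector `"ROI001"`, ... .
#' @export
roi_labels <- function(m) sprintf("ROI%03d", seq_len(m))

#' Contiguous equal-block module assignment
#'
#' ROIs are split into `n_modules` contiguous blocks of `floor(m / n_modules)`
#' ROIs; remainder ROIs go to the last module.
#'
#' @param m Number of ROIs.
#' @param n_modules Number of modules.
#' @return Integer vector of length `m` with values in `1..n_modules`.
#' @export
module_assignment <- function(m, n_modules) {
  block <- m %/% n_modules
  mod <- pmin(((seq_len(m) - 1L) %/% block) + 1L, n_modules)
  as.integer(mod)
}

# per-subject seed: documented counter scheme (prime stride keeps subject
# streams distinct for any master seed; modulus keeps the value a valid
# 32-bit integer)
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * i) %% .Machine$integer.max)
}

# band-limited latent: moving-average-smoothed white noise, unit variance.
# window of 5 samples (10 s at TR 2 s) mimics the slow dynamics of
# high-pass-filtered BOLD.
latent_signal <- function(n, window = 5L) {
  z <- stats::rnorm(n + window - 1L)
  z <- stats::filter(z, rep(1 / window, window), sides = 1)
  z <- as.numeric(z[window:(n + window - 1L)])
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic two-group cohort
#'
#' Simulates every subject described by a [synthetic_spec()]: controls first
#' (label 0), then patients (label 1).  Deterministic given the spec,
#' including `master_seed`; per-subject seeds are derived from the master
#' seed by a fixed counter scheme, so subjects are independent and any
#' single subject is reproducible in isolation.
#'
#' Cross-module lags are applied by shifting (truncating, not wrapping) the
#' latent series, consistent with the non-circular cross-correlation
#' estimator used downstream.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [roi_ts()] objects of length `n_controls + n_patients`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    abort_embedfcn("spec must be a synthetic_spec", "embedfcn_validation_error")
  m <- spec$n_rois; tt <- spec$n_timepoints
  mods <- module_assignment(m, spec$n_modules)
  labels <- roi_labels(m)
  max_lag <- 3L

  # fixed per-cohort wiring: designated cross-module target, lag, and
  # connector-hub flag per ROI.  Connector hubs (a fixed 15% of ROIs)
  # couple to their target module as strongly as to their own; they
  # emulate the inter-network hub regions that keep empirical k-NN
  # graphs connected.
  connector_fraction <- 0.25
  pn <- spec$planted_nodes
  lower_idx <- if (is.null(pn)) integer() else
    pn$roi_index[pn$effect == "lower_strength"]
  raise_idx <- if (is.null(pn)) integer() else
    pn$roi_index[pn$effect == "raise_participation"]
  wiring <- withr::with_seed(subject_seed(spec$master_seed, 0L), {
    target <- vapply(seq_len(m), function(i) {
      others <- setdiff(seq_len(spec$n_modules), mods[i])
      if (length(others) == 0L) mods[i] else sample(others, 1L)
    }, integer(1L))
    lag <- integer(m)
    lagged <- stats::runif(m) < spec$lag_fraction
    lag[lagged] <- sample(1:3, sum(lagged), replace = TRUE)
    connector <- stats::runif(m) < connector_fraction
    # planted nodes get controlled baselines: lower_strength nodes start
    # from the plain modular profile; a raise_participation node is an
    # integrative hub coupled evenly to its own and one partner module
    # (the clinically familiar picture: an already-integrative region
    # whose coupling spreads further in patients, into a held-out third
    # module)
    connector[lower_idx] <- FALSE
    connector[raise_idx] <- FALSE
    partner <- rep(NA_integer_, m)
    holdout <- rep(NA_integer_, m)
    for (ri in raise_idx) {
      others <- setdiff(seq_len(spec$n_modules), mods[ri])
      if (length(others) > 0L) partner[ri] <- sample(others, 1L)
      rest <- setdiff(others, partner[ri])
      if (length(rest) > 0L) holdout[ri] <- sample(rest, 1L)
    }
    list(target = target, lag = lag, connector = connector,
         partner = partner, holdout = holdout)
  })

  n_total <- spec$n_controls + spec$n_patients
  group <- c(rep(0L, spec$n_controls), rep(1L, spec$n_patients))
  lapply(seq_len(n_total), function(s) {
    g <- group[s] + 1L   # 1 = control, 2 = patient
    withr::with_seed(subject_seed(spec$master_seed, s), {
      z <- vapply(seq_len(spec$n_modules), function(mm) latent_signal(tt + max_lag),
                  numeric(tt + max_lag))
      base_within <- spec$within_module_coupling[g]
      within <- rep(base_within, m)
      cross <- rep(spec$cross_module_coupling[g], m)
      cross[wiring$connector] <- base_within
      extra_es <- rep(0, m)       # raise_participation coefficient per ROI
      if (!is.null(spec$planted_nodes)) {
        n_pl <- nrow(spec$planted_nodes)
        # patients express every planted effect in full; 20% of controls
        # are subclinical carriers of ONE planted effect (chosen at
        # random) -- the single-marker overlap that makes individual
        # biomarkers unspecific, while no control is aberrant on every
        # marker at once.  Subclinical carriers express their one marker
        # partially (severity drawn from U(0.5, 0.75)), landing inside
        # the decision margin: single planted markers get genuine false
        # positives while the marker pair stays jointly separable.
        apply_to <- integer()
        sev <- 1
        if (group[s] == 1L) {
          apply_to <- seq_len(n_pl)
        } else if (stats::runif(1L) < 0.20) {
          apply_to <- sample.int(n_pl, 1L)
          sev <- stats::runif(1L, 0.5, 0.75)
        }
        for (r in apply_to) {
          ri <- spec$planted_nodes$roi_index[r]
          es <- spec$planted_nodes$effect_size[r] * sev
          if (spec$planted_nodes$effect[r] == "lower_strength") {
            shrink <- max(0, 1 - es)
            within[ri] <- within[ri] * shrink
            cross[ri] <- cross[ri] * shrink
          } else {
            extra_es[ri] <- es
          }
        }
      }
      x <- matrix(0, tt, m, dimnames = list(NULL, labels))
      for (i in seq_len(m)) {
        own <- z[1:tt, mods[i]]
        if (i %in% raise_idx && !is.na(wiring$partner[i])) {
          # integrative-hub baseline: even coupling to the own and one
          # partner module; the planted effect spreads into every
          # remaining module at the effect coefficient, then the
          # profile is rescaled so the node's total coupling energy is
          # fixed -- participation rises, strength does not
          xi <- within[i] * own + within[i] * z[1:tt, wiring$partner[i]]
          e0 <- 2 * within[i]^2
          if (extra_es[i] > 0) {
            rest <- setdiff(seq_len(spec$n_modules),
                            c(mods[i], wiring$partner[i]))
            for (mm in rest) xi <- xi + extra_es[i] * z[1:tt, mm]
            e1 <- e0 + length(rest) * extra_es[i]^2
            if (e1 > 0) xi <- xi * sqrt(e0 / e1)
          }
        } else {
          l <- wiring$lag[i]
          crs <- z[(1L + l):(tt + l), wiring$target[i]]
          xi <- within[i] * own + cross[i] * crs
        }
        x[, i] <- xi + stats::rnorm(tt, sd = spec$noise_sd)
      }
      roi_ts(sprintf("S%03d", s), group[s], x, spec$tr_seconds)
    })
  })
}

#' Ground truth of planted group differences
#'
#' Maps each planted node of a [synthetic_spec()] to the node measure it is
#' expected to shift: `raise_participation` to `"participation"` (higher in
#' patients) and `lower_strength` to `"strength"` (lower in patients).
#' Order follows `planted_nodes`.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `measure`, `roi_index`, `feature`
#'   (the corresponding feature-vector name).
#' @export
planted_truth <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    abort_embedfcn("spec must be a synthetic_spec", "embedfcn_validation_error")
  pn <- spec$planted_nodes
  if (is.null(pn) || nrow(pn) == 0L)
    return(data.frame(measure = character(), roi_index = integer(),
                      feature = character(), stringsAsFactors = FALSE))
  measure <- ifelse(pn$effect == "raise_participation", "participation", "strength")
  prefix <- ifelse(measure == "participation", "Pc", "St")
  data.frame(
    measure = measure,
    roi_index = as.integer(pn$roi_index),
    feature = paste0(prefix, ":", roi_labels(spec$n_rois)[pn$roi_index]),
    stringsAsFactors = FALSE
  )
}
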