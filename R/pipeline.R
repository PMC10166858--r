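#' Segmentation run configuration
#'
#' Collects every hyperparameter of the segmentation pipeline in one
#' validated list, serialized alongside every output for provenance. The
#' two that always matter are the subsequence length `nw` (long enough to
#' capture regime-specific shape, short enough that most windows sit inside
#' one segment) and the temporal constraint `tc` (roughly the maximum
#' expected segment length; mandatory for the latent-space method, and what
#' makes repeated regime types segmentable).
#'
#' @param nw Subsequence (window) length in time steps.
#' @param tc Temporal-constraint radius in positions; `Inf` allowed only
#'   for the raw-profile baseline.
#' @param method `"lsuss"` (latent-space), `"fluss"` (channel-averaged raw
#'   profile), or `"lfmd"` (adjacent-window latent distance).
#' @param direction `"bidirectional"` (offline) or `"forward"` (streaming,
#'   arcs point to newer data only).
#' @param extractor `"lrea"`, `"rea"`, or `"ltea"`.
#' @param k Number of change-points (required by rea/lrea).
#' @param local_window Rolling half-width for lrea/ltea scaling; a good
#'   choice is the mean gap between training-set change-points.
#' @param threshold ltea cut on the scaled curve (default -1).
#' @param excl_width Extractor exclusion radius; default `5 * nw`.
#' @param excl Profile trivial-match exclusion radius; default
#'   `ceiling(nw / 4)`.
#' @param t_lim Chunk length for the batched profile computation (optional).
#' @param epsilon_batch Samples accumulated per streaming append; the
#'   epsilon of epsilon-real-time detection latency. Default 1 in forward
#'   mode (fully online) and `t_lim - (2 tc - 1)` bidirectionally.
#' @param scaling_mode Rolling-statistics mode for the ltea extractor:
#'   `"centered"` (default; extraction over a completed curve) or
#'   `"trailing"` (past-only statistics, what an emit-as-you-go streaming
#'   consumer could maintain).
#' @param lfmd_overlap Window overlap for the lfmd baseline.
#' @param iac_trials Monte-Carlo trials for simulated idealized arc curves.
#' @param seed Seed for every stochastic step of the run.
#' @param interpretation Prediction-loss combination rule, see
#'   [prediction_loss_mae()].
#' @return List of class `lss_config` with a `hash` field.
#' @export
segmentation_config <- function(nw, tc,
                                method = c("lsuss", "fluss", "lfmd"),
                                direction = c("bidirectional", "forward"),
                                extractor = c("lrea", "rea", "ltea"),
                                k = NULL, local_window = NULL, threshold = -1,
                                excl_width = NULL, excl = NULL,
                                scaling_mode = c("centered", "trailing"),
                                t_lim = NULL, epsilon_batch = NULL,
                                lfmd_overlap = 0L, iac_trials = 1000L,
                                seed = 1L,
                                interpretation = "inflation_default") {
  method <- match.arg(method)
  direction <- match.arg(direction)
  extractor <- match.arg(extractor)
  scaling_mode <- match.arg(scaling_mode)
  nw <- as.integer(nw)
  if (nw < 2) abort("nw must be >= 2")
  excl <- as.integer(excl %||% default_exclusion(nw))
  excl_width <- as.integer(excl_width %||% (5L * nw))
  if (method == "lsuss" && !is.finite(tc)) {
    abort("the latent-space method requires a finite temporal constraint tc")
  }
  if (is.finite(tc) && tc <= excl) {
    abort("tc must exceed the profile exclusion radius excl")
  }
  if (extractor %in% c("rea", "lrea") && is.null(k)) {
    abort(sprintf("extractor '%s' requires k, the number of change-points", extractor))
  }
  if (extractor %in% c("lrea", "ltea") && is.null(local_window)) {
    abort(sprintf("extractor '%s' requires local_window (e.g. the mean change-point gap of a training set)", extractor))
  }
  if (!is.null(t_lim) && is.finite(tc) && t_lim <= 2 * tc) {
    abort("t_lim must exceed 2 * tc")
  }
  if (is.null(epsilon_batch)) {
    epsilon_batch <- if (direction == "forward") 1L
    else if (!is.null(t_lim)) as.integer(t_lim - (2L * as.integer(tc) - 1L))
    else NULL
  }
  cfg <- list(nw = nw, tc = tc, method = method, direction = direction,
              extractor = extractor, k = k, local_window = local_window,
              threshold = threshold, excl_width = excl_width, excl = excl,
              scaling_mode = scaling_mode,
              t_lim = t_lim, epsilon_batch = epsilon_batch,
              lfmd_overlap = as.integer(lfmd_overlap),
              iac_trials = as.integer(iac_trials), seed = as.integer(seed),
              interpretation = interpretation)
  cfg$hash <- hash(cfg)
  structure(cfg, class = "lss_config")
}

#' @export
print.lss_config <- function(x, ...) {
  cat(sprintf("<lss_config> %s/%s/%s, nw = %d, tc = %s [hash %s]\n",
              x$method, x$direction, x$extractor, x$nw,
              if (is.finite(x$tc)) format(x$tc) else "unconstrained",
              substr(x$hash, 1, 8)))
  invisible(x)
}

extract_changepoints <- function(cac, config) {
  switch(config$extractor,
    rea = rea(cac, config$k, config$excl_width),
    lrea = lrea(cac, config$k, config$local_window, config$excl_width),
    ltea = ltea(cac, config$local_window, config$threshold,
                config$excl_width, config$scaling_mode)
  )
}

#' Segment a multichannel time series (offline)
#'
#' Runs the configured segmentation pipeline end to end on a complete
#' series: encode all subsequences (latent method), compute the
#' (temporally constrained) matrix profile, normalize its arc counts into a
#' corrected arc curve, and extract change-points. A change-point is
#' reported at the subsequence position whose curve valley marks the
#' transition.
#'
#' @param x Series: data frame (one row per step, columns = channels),
#'   matrix, or vector.
#' @param config [segmentation_config()].
#' @param model Trained [train_autoencoder()] model; required for the
#'   `"lsuss"` and `"lfmd"` methods.
#' @return Object of class `lss_segmentation`: list with `changepoints`
#'   (integer), `cac` (`lss_cac` or `NULL` for lfmd), `config`, `method`,
#'   `n`, and `profile` (the matrix profile, when one was computed).
#' @export
#' @seealso [segment_stream()] for the streaming replay,
#'   [score_segmentation()] to evaluate against ground truth.
segment_ts <- function(x, config, model = NULL) {
  stopifnot(inherits(config, "lss_config"))
  xm <- as_ts_matrix(x)
  n <- nrow(xm)
  if (config$method %in% c("lsuss", "lfmd") && is.null(model)) {
    abort(sprintf("method '%s' requires a trained autoencoder model", config$method))
  }
  if (!is.null(model) && model$spec$nw != config$nw) {
    abort(sprintf("config nw = %d does not match the model's nw = %d",
                  config$nw, model$spec$nw))
  }
  if (config$method == "lfmd") {
    cps <- lfmd_changepoints(x, model, overlap = config$lfmd_overlap)
    return(new_segmentation(cps, cac = NULL, profile = NULL,
                            config = config, n = n))
  }
  if (config$method == "lsuss") {
    f <- encode_all(model, xm)
    if (!is.null(config$t_lim)) {
      mp <- batched_collapse(f, config$t_lim, config$tc,
                             direction = config$direction, excl = config$excl)
    } else {
      mp <- lsmp_full(f, config$tc, direction = config$direction,
                      excl = config$excl)
    }
    cac <- cac_from_profile(mp, n_trials = config$iac_trials,
                            seed = config$seed)
  } else {
    cac <- fluss_cac(xm, m = config$nw, tc = config$tc,
                     direction = config$direction, excl = config$excl,
                     n_trials = config$iac_trials, seed = config$seed)
    mp <- NULL
  }
  cps <- extract_changepoints(cac, config)
  new_segmentation(cps, cac = cac,
                   profile = if (config$method == "lsuss") mp else NULL,
                   config = config, n = n)
}

#' Segment a series replayed as a stream (epsilon-real-time)
#'
#' Replays the series in chunks of `epsilon_batch` samples through the
#' incremental latent-space profile: each chunk's newly completed windows
#' are encoded and appended, and existing profile entries are updated in
#' place. With `direction = "forward"` the run is fully online (arcs point
#' only to newer data, the one-directional idealized curve normalizes the
#' counts); change-points are then extracted from the final curve with the
#' trailing (past-only) scaling a streaming consumer could maintain.
#'
#' @inheritParams segment_ts
#' @return An `lss_segmentation`.
#' @export
segment_stream <- function(x, config, model) {
  stopifnot(inherits(config, "lss_config"))
  if (config$method != "lsuss") {
    abort("segment_stream implements the latent-space method; use segment_ts for the baselines")
  }
  if (is.null(model)) abort("segment_stream requires a trained autoencoder model")
  xm <- as_ts_matrix(x)
  n <- nrow(xm)
  nw <- config$nw
  eps <- max(1L, as.integer(config$epsilon_batch %||% 1L))
  state <- NULL
  raw_tail <- NULL
  for (start in seq(1L, n, by = eps)) {
    block <- rbind(raw_tail, xm[start:min(start + eps - 1L, n), , drop = FALSE])
    if (nrow(block) >= nw) {
      f_new <- encode_all(model, block)
      attr(f_new, "m") <- NULL
      if (is.null(state)) {
        state <- lsmp_online_init(f_new, config$tc,
                                  direction = config$direction,
                                  excl = config$excl)
      } else {
        state <- lsmp_online_append(state, f_new)
      }
      raw_tail <- block[(nrow(block) - nw + 2L):nrow(block), , drop = FALSE]
    } else {
      raw_tail <- block
    }
  }
  if (is.null(state)) abort("series shorter than one window; nothing to segment")
  mp <- lsmp_online_profile(state, m = nw)
  cac <- cac_from_profile(mp, n_trials = config$iac_trials, seed = config$seed)
  cps <- extract_changepoints(cac, config)
  new_segmentation(cps, cac = cac, profile = mp, config = config, n = n)
}

new_segmentation <- function(changepoints, cac, profile, config, n) {
  structure(
    list(changepoints = as.integer(changepoints), cac = cac,
         profile = profile, config = config, n = n),
    class = "lss_segmentation"
  )
}

#' @export
print.lss_segmentation <- function(x, ...) {
  cat(sprintf("<lss_segmentation> %s/%s/%s on %d steps: %d change-point(s)%s\n",
              x$config$method, x$config$direction, x$config$extractor, x$n,
              length(x$changepoints),
              if (length(x$changepoints)) paste0(" at ",
                paste(x$changepoints, collapse = ", ")) else ""))
  invisible(x)
}

#' @describeIn segment_ts One row per detected change-point, with the local
#'   curve value.
#' @param x,... Method arguments.
#' @export
tidy.lss_segmentation <- function(x, ...) {
  tibble(
    changepoint = x$changepoints,
    cac = if (is.null(x$cac)) NA_real_ else as.numeric(x$cac)[x$changepoints]
  )
}

#' @describeIn segment_ts One-row run summary.
#' @export
glance.lss_segmentation <- function(x, ...) {
  tibble(
    method = x$config$method, direction = x$config$direction,
    extractor = x$config$extractor, nw = x$config$nw, tc = x$config$tc,
    n = x$n, n_changepoints = length(x$changepoints),
    min_cac = if (is.null(x$cac)) NA_real_ else min(x$cac),
    config_hash = x$config$hash
  )
}

## ---- file formats ----------------------------------------------------------

#' Read a multichannel time series from delimited text
#'
#' One row per time step, one numeric column per channel, optional header.
#'
#' @param path File path.
#' @param header Whether the first line holds channel names.
#' @param delim Field delimiter.
#' @return Tibble of numeric channels.
#' @export
read_timeseries <- function(path, header = TRUE, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = delim, col_names = header,
                          show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("parse error in %s: %s (first at line %d)",
                  path, pr$expected[1], pr$row[1]))
  }
  if (nrow(df) == 0) abort(sprintf("empty time series file: %s", path))
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(sprintf("non-numeric column(s) in %s: %s", path,
                  paste(non_num, collapse = ", ")))
  }
  df
}

#' Write a time series as delimited text
#' @param x Series (data frame or matrix).
#' @param path Destination.
#' @export
write_timeseries <- function(x, path) {
  xm <- as_ts_matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- sprintf("ch%02d", seq_len(ncol(xm)))
  readr::write_csv(as_tibble(xm), path)
  invisible(path)
}

#' Read / write change-point index files
#'
#' One non-negative integer per line, strictly increasing; an empty file is
#' a valid empty set.
#'
#' @param path File path.
#' @param n Optional series length for bounds validation.
#' @return Integer vector.
#' @export
read_changepoints <- function(path, n = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(integer(0))
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals))) {
    abort(sprintf("non-integer line %d in %s: '%s'",
                  which(is.na(vals))[1], path, lines[which(is.na(vals))[1]]))
  }
  validate_changepoints(vals, n)
}

#' @rdname read_changepoints
#' @param cp Integer vector of change-points.
#' @export
write_changepoints <- function(cp, path) {
  cp <- validate_changepoints(cp)
  writeLines(as.character(cp), path)
  invisible(path)
}

#' Write a segmentation run's artifacts
#'
#' Writes the corrected arc curve (CSV), the change-points (one index per
#' line) and the resolved configuration (YAML, including its hash) into a
#' directory, so any run can be reproduced from its recorded config.
#'
#' @param seg An `lss_segmentation`.
#' @param dir Output directory (created if needed).
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "lss_segmentation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seg$cac)) {
    readr::write_csv(as_tibble(seg$cac), file.path(dir, "cac.csv"))
  }
  write_changepoints(seg$changepoints, file.path(dir, "changepoints.txt"))
  cfg <- unclass(seg$config)
  cfg$tc <- if (is.finite(cfg$tc)) cfg$tc else "unconstrained"
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
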