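# Reduction of Next Generation Impactor (NGI) stage-mass tables to
# aerodynamic descriptors: emitted dose, fine particle mass/fraction and the
# log-normal MMAD/GSD obtained from a probit regression of the cumulative
# undersize distribution.

#' Locations of an NGI stage-mass table
#'
#' Column order used throughout the package for the drug mass recovered at
#' each impactor location (mg).
#'
#' @export
ngi_locations <- c("device_residue", "induction_port", "pre_separator",
                   paste0("stage", 1:7), "moc")

.ngi_sized <- c(paste0("stage", 1:7), "moc")

#' Create a stage-mass table for one impactor run
#'
#' @param run_id Character run identifier.
#' @param device `"capsule"` or `"reservoir"`.
#' @param flow Volumetric flow through the impactor (L/min).
#' @param masses Named numeric vector of drug masses (mg); names must cover
#'   all of [ngi_locations]. Zero masses are allowed.
#' @return A `stage_mass_table` object (a one-row list with validated fields).
#' @export
stage_mass_table <- function(run_id, device = c("capsule", "reservoir"),
                             flow, masses) {
  device <- match.arg(device)
  if (!is.numeric(flow) || length(flow) != 1L || !is.finite(flow) || flow <= 0)
    stop("`flow` must be a single positive number (L/min)")
  missing_loc <- setdiff(ngi_locations, names(masses))
  if (length(missing_loc))
    stop("missing impactor locations: ", paste(missing_loc, collapse = ", "))
  m <- as.numeric(masses[ngi_locations])
  names(m) <- ngi_locations
  if (any(!is.finite(m)) || any(m < 0))
    stop("all stage masses must be finite and >= 0")
  structure(list(run_id = as.character(run_id), device = device,
                 flow = flow, masses = m),
            class = "stage_mass_table")
}

.cutoff_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ngi_cutoffs_60lpm.csv", package = "dpipk")
      cache <<- utils::read.csv(path, comment.char = "#")
    }
    cache
  }
})

#' NGI stage cut-off diameters at a given flow
#'
#' Scales the archival 60 L/min stage calibration to the working flow with
#' the per-stage power law d50(Q) = d50_ref * (60/Q)^x. The calibration is
#' considered valid for flows between 15 and 100 L/min; outside that window a
#' warning is emitted but the power law is still applied.
#'
#' @param flow Volumetric flow (L/min), > 0.
#' @return A `cutoff_set`: list with `flow` and `d50` (named numeric vector of
#'   the seven stage cut-offs, um, strictly decreasing). The MOC is treated as
#'   collecting everything below the stage 7 cut-off.
#' @export
ngi_cutoffs <- function(flow) {
  if (!is.numeric(flow) || length(flow) != 1L || !is.finite(flow) || flow <= 0)
    stop("`flow` must be a single positive number (L/min)")
  if (flow < 15 || flow > 100)
    warning("flow ", flow, " L/min is outside the 15-100 L/min calibration window")
  tab <- .cutoff_table()
  d50 <- tab$d50_um * (60 / flow)^tab$exponent
  names(d50) <- paste0("stage", tab$stage)
  stopifnot(all(diff(d50) < 0))
  structure(list(flow = flow, d50 = d50), class = "cutoff_set")
}

#' Emitted dose of one run
#'
#' The emitted dose (ED) is the drug mass leaving the device: the sum of all
#' recovered masses except the device/capsule residue.
#'
#' @param table A [stage_mass_table()].
#' @return ED in mg.
#' @export
emitted_dose <- function(table) {
  stopifnot(inherits(table, "stage_mass_table"))
  sum(table$masses[setdiff(ngi_locations, "device_residue")])
}

#' Cumulative undersize distribution of the impactor-sized mass
#'
#' Returns, for each stage cut-off, the fraction of the sized mass
#' (stages 1-7 plus MOC; induction port and pre-separator are excluded
#' because no cut-off is defined for them) with aerodynamic diameter below
#' that cut-off.
#'
#' @param table A [stage_mass_table()].
#' @param cutoffs A [ngi_cutoffs()] result; defaults to the cut-offs at the
#'   run's own flow.
#' @return A data frame with columns `diameter_um` (increasing) and
#'   `fraction` (nondecreasing cumulative mass fraction).
#' @export
cumulative_undersize <- function(table, cutoffs = ngi_cutoffs(table$flow)) {
  stopifnot(inherits(table, "stage_mass_table"), inherits(cutoffs, "cutoff_set"))
  m <- table$masses[.ngi_sized]
  total <- sum(m)
  if (total <= 0) stop("zero sized mass: undersize distribution undefined")
  # mass below the cut-off of stage i = everything collected downstream of it
  below <- rev(cumsum(rev(m)))[-1L]          # stages 2..7 + moc, 3..7 + moc, ...
  frac <- as.numeric(below) / total
  data.frame(diameter_um = rev(as.numeric(cutoffs$d50)),
             fraction = rev(frac))
}

#' Fit a log-normal aerodynamic size distribution by probit regression
#'
#' Regresses probit(cumulative fraction) on ln(diameter) by least squares.
#' The MMAD is the diameter at probit zero (the mass median) and
#' GSD = exp(1/slope). Points with fraction at or outside (0, 1) are excluded.
#'
#' @param cumulative Data frame with columns `diameter_um` and `fraction`
#'   (as returned by [cumulative_undersize()]).
#' @return List with `mmad` (um), `gsd`, `fit_r2`, and the `slope` and
#'   `intercept` of the probit line.
#' @export
fit_lognormal <- function(cumulative) {
  d <- cumulative$diameter_um
  f <- cumulative$fraction
  # fractions numerically indistinguishable from 0 or 1 carry no usable
  # probit information (the quantile derivative amplifies double rounding)
  eps <- 1e-7
  keep <- is.finite(d) & is.finite(f) & f > eps & f < 1 - eps
  if (sum(keep) < 3L)
    stop("insufficient data: need >= 3 cumulative points strictly inside (0, 1)")
  x <- log(d[keep])
  y <- stats::qnorm(f[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- fit$coefficients
  if (!is.finite(b[2L]) || b[2L] <= 0)
    stop("degenerate distribution: nonpositive probit slope")
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(mmad = exp(-b[[1L]] / b[[2L]]), gsd = exp(1 / b[[2L]]),
       fit_r2 = r2, slope = b[[2L]], intercept = b[[1L]])
}

#' Fine particle mass of one run
#'
#' Mass of drug with aerodynamic diameter between `lo` and `hi` (default
#' 1-5 um): the sized mass multiplied by the band probability of the fitted
#' log-normal, evaluated on the probit--ln(d) regression line.
#'
#' @inheritParams cumulative_undersize
#' @param lo,hi Band limits in um.
#' @return FPM in mg.
#' @export
fine_particle_mass <- function(table, cutoffs = ngi_cutoffs(table$flow),
                               lo = 1, hi = 5) {
  cum <- cumulative_undersize(table, cutoffs)
  fit <- fit_lognormal(cum)
  sized <- sum(table$masses[.ngi_sized])
  u <- function(d) stats::pnorm(fit$intercept + fit$slope * log(d))
  sized * (u(hi) - u(lo))
}

#' Fine particle fraction
#'
#' @param fpm Fine particle mass (mg).
#' @param ed Emitted dose (mg), > 0.
#' @return FPF as a percentage of the emitted dose.
#' @export
fine_particle_fraction <- function(fpm, ed) {
  if (ed <= 0) stop("undefined ratio: emitted dose must be > 0")
  100 * fpm / ed
}

#' Reduce one impactor run to its aerodynamic summary
#'
#' @param table A [stage_mass_table()].
#' @return One-row data frame with `run_id`, `ED_mg`, `FPM_mg`, `FPF_pct`,
#'   `MMAD_um`, `GSD`, `fit_r2`.
#' @export
aerodynamic_summary <- function(table) {
  cutoffs <- ngi_cutoffs(table$flow)
  ed <- emitted_dose(table)
  fit <- fit_lognormal(cumulative_undersize(table, cutoffs))
  fpm <- fine_particle_mass(table, cutoffs)
  data.frame(run_id = table$run_id, ED_mg = ed, FPM_mg = fpm,
             FPF_pct = fine_particle_fraction(fpm, ed),
             MMAD_um = fit$mmad, GSD = fit$gsd, fit_r2 = fit$fit_r2)
}

#' Read impactor runs from a delimited text file
#'
#' Expected comma-separated columns: `run_id`, `device`, `flow_lpm`,
#' `device_residue_mg`, `induction_port_mg`, `pre_separator_mg`,
#' `stage1_mg` ... `stage7_mg`, `moc_mg`.
#'
#' @param path File path.
#' @return List of [stage_mass_table()] objects.
#' @export
read_ngi_runs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "device", "flow_lpm", paste0(ngi_locations, "_mg"))
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop("missing columns: ", paste(missing_col, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    m <- as.numeric(df[i, paste0(ngi_locations, "_mg")])
    names(m) <- ngi_locations
    stage_mass_table(df$run_id[i], df$device[i], df$flow_lpm[i], m)
  })
}

#' Reduce a set of runs, optionally averaging replicates
#'
#' Summaries are computed per run; when `per_replicate = FALSE` replicate runs
#' sharing a `group` label are averaged and reported as mean with SD and n,
#' matching the usual "n = 3, mean +/- SD" presentation of impactor data.
#'
#' @param runs List of [stage_mass_table()] objects.
#' @param groups Optional character vector (same length as `runs`) of
#'   formulation labels; defaults to each run's id (no pooling).
#' @param per_replicate If `TRUE`, return the per-run table unaggregated.
#' @return Data frame of aerodynamic summaries.
#' @export
reduce_ngi_runs <- function(runs, groups = NULL, per_replicate = FALSE) {
  per <- do.call(rbind, lapply(runs, aerodynamic_summary))
  if (per_replicate || is.null(groups)) return(per)
  stopifnot(length(groups) == length(runs))
  per$group <- groups
  num <- c("ED_mg", "FPM_mg", "FPF_pct", "MMAD_um", "GSD", "fit_r2")
  out <- do.call(rbind, lapply(split(per, per$group), function(g) {
    means <- vapply(g[num], mean, numeric(1))
    sds <- vapply(g[num], stats::sd, numeric(1))
    cbind(data.frame(group = g$group[1L], n = nrow(g)),
          as.data.frame(as.list(means)),
          stats::setNames(as.data.frame(as.list(sds)), paste0(num, "_sd")))
  }))
  rownames(out) <- NULL
  out
}
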