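# Synthetic-data generators: NGI runs drawn from a log-normal aerodynamic
# size distribution with multiplicative replicate noise, and powder
# descriptor tables with a controllable property-outcome correlation
# structure. One global integer seed drives named substreams so that adding
# replicates or materials never perturbs earlier draws.

# deterministic substream seed from (seed, stream name), kept below 2^31
.stream_seed <- function(seed, name) {
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 2147483629
  as.integer((seed %% 2147483629 + h * 7919) %% 2147483629 + 1)
}

.with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(.stream_seed(seed, name))
  expr
}

#' Generate synthetic NGI runs for one formulation
#'
#' Apportions the sized mass (stages 1-7 + MOC) by log-normal CDF
#' differences at the flow-correct stage cut-offs, with stage 1 additionally
#' collecting the mass coarser than its own cut-off so that the cumulative
#' undersize of the sized mass equals the untruncated log-normal CDF (and the
#' probit fit recovers the generator parameters exactly at zero noise).
#' Induction port and pre-separator receive the non-sized part of the
#' emitted dose. Multiplicative log-normal noise with coefficient of
#' variation `cv` is applied independently per collection surface.
#'
#' @param mmad,gsd True aerodynamic distribution parameters (um, -).
#' @param ed_mg Target emitted dose (mg).
#' @param residue_mg Device/capsule residue (mg).
#' @param flow Test flow (L/min).
#' @param device `"capsule"` or `"reservoir"`.
#' @param sized_frac Fraction of the emitted dose reaching the sized
#'   surfaces; the remainder splits between induction port and pre-separator
#'   in proportion `ip_ps_split`.
#' @param ip_ps_split Induction-port share of the non-sized emitted dose.
#' @param cv Per-surface multiplicative noise CV (0 = exact).
#' @param n_rep Number of replicate runs.
#' @param seed Integer seed.
#' @param label Formulation label used for run ids and the noise stream.
#' @return List of [stage_mass_table()] objects, length `n_rep`.
#' @export
gen_ngi_run <- function(mmad, gsd, ed_mg, residue_mg = 0.5, flow = 60,
                        device = "capsule", sized_frac = 0.31,
                        ip_ps_split = 0.65, cv = 0, n_rep = 1L, seed = 1L,
                        label = "synth") {
  stopifnot(mmad > 0, gsd >= 1, ed_mg >= 0, residue_mg >= 0, cv >= 0,
            sized_frac >= 0, sized_frac <= 1, ip_ps_split >= 0, ip_ps_split <= 1)
  cutoffs <- ngi_cutoffs(flow)
  d50 <- as.numeric(cutoffs$d50)
  cdf <- if (gsd == 1) as.numeric(d50 > mmad) else
    stats::pnorm(log(d50), log(mmad), log(gsd))
  sized <- ed_mg * sized_frac
  stage_mass <- sized * c(1 - cdf[1L], -diff(cdf))    # stages 1..7
  moc <- sized * cdf[7L]
  nonsized <- ed_mg - sized
  base <- c(device_residue = residue_mg,
            induction_port = nonsized * ip_ps_split,
            pre_separator = nonsized * (1 - ip_ps_split),
            stats::setNames(stage_mass, paste0("stage", 1:7)),
            moc = moc)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  lapply(seq_len(n_rep), function(i) {
    m <- if (cv > 0) {
      .with_stream(seed, paste0(label, "/rep", i),
                   base * exp(stats::rnorm(length(base), -sdlog^2 / 2, sdlog)))
    } else base
    stage_mass_table(sprintf("%s_r%d", label, i), device, flow, m)
  })
}

#' Generate correlated property and outcome descriptor tables
#'
#' Draws jointly Gaussian columns: each outcome column shares the latent
#' variable of its paired property column (pairing by recycling) with target
#' correlation `rho`.
#'
#' @param n_rows Number of materials (4 mimics a 4-carrier design).
#' @param rho Target property-outcome correlation, |rho| <= 1.
#' @param prop_names,outcome_names Column names.
#' @param prop_means,prop_sds,outcome_means,outcome_sds Column moments,
#'   recycled to the number of columns.
#' @param seed Integer seed.
#' @return List with data frames `props` and `outcomes` (row names =
#'   material ids).
#' @export
gen_descriptor_tables <- function(n_rows = 4L, rho = 0.8,
                                  prop_names = c("Dv0.5", "FinesPct", "SSA",
                                                 "PoreV", "PoreS", "Alpha",
                                                 "TS", "Coh", "FF", "sSSi",
                                                 "dSSi", "sCPS", "dCPS",
                                                 "sPD", "dPD"),
                                  outcome_names = c("ED", "FPM", "FPF",
                                                    "MMAD", "Lung", "Ext",
                                                    "Cmax", "tmax",
                                                    "AUC_0_12", "ConcU"),
                                  prop_means = 10, prop_sds = 2,
                                  outcome_means = 5, outcome_sds = 1,
                                  seed = 1L) {
  stopifnot(abs(rho) <= 1, n_rows >= 2)
  np <- length(prop_names); no <- length(outcome_names)
  prop_means <- rep_len(prop_means, np); prop_sds <- rep_len(prop_sds, np)
  outcome_means <- rep_len(outcome_means, no)
  outcome_sds <- rep_len(outcome_sds, no)
  z <- vapply(seq_len(np), function(j)
    .with_stream(seed, paste0("prop/", prop_names[j]), stats::rnorm(n_rows)),
    numeric(n_rows))
  props <- sweep(sweep(z, 2, prop_sds, "*"), 2, prop_means, "+")
  colnames(props) <- prop_names
  outcomes <- vapply(seq_len(no), function(j) {
    jz <- ((j - 1L) %% np) + 1L
    e <- .with_stream(seed, paste0("outcome/", outcome_names[j]),
                      stats::rnorm(n_rows))
    outcome_means[j] + outcome_sds[j] * (rho * z[, jz] + sqrt(1 - rho^2) * e)
  }, numeric(n_rows))
  colnames(outcomes) <- outcome_names
  ids <- paste0("material", seq_len(n_rows))
  props <- as.data.frame(props, row.names = ids)
  outcomes <- as.data.frame(outcomes, row.names = ids)
  list(props = props, outcomes = outcomes)
}

#' Write stage-mass tables to the package's delimited run format
#'
#' @param runs List of [stage_mass_table()] objects.
#' @param path Output CSV path.
#' @export
write_ngi_runs <- function(runs, path) {
  rows <- lapply(runs, function(r) {
    cbind(data.frame(run_id = r$run_id, device = r$device, flow_lpm = r$flow),
          stats::setNames(as.data.frame(as.list(r$masses)),
                          paste0(ngi_locations, "_mg")))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
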