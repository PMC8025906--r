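# Parameter containers for the inhaled-salbutamol PBPK model. Defaults are
# the salbutamol sulphate value set used throughout: physicochemistry and
# permeabilities from the published characterization of the compound,
# clearances and lung-disposition fractions from the fitted
# inhalation model, and regional lining-fluid volumes / absorptive surface
# areas as bundled physiology defaults (see the methods vignette for their
# provenance and role).

#' Drug-specific parameters
#'
#' @param MW Molecular weight (g/mol).
#' @param logP Octanol-water log partition coefficient of the neutral species.
#' @param pKa Basic dissociation constants (diprotic base convention).
#' @param ref_solubility Aqueous solubility at pH 7.4 (mg/mL).
#' @param lung_solubility Solubility in simulated lung fluid (mg/mL).
#' @param Papp_bronchiolar Apparent permeability, bronchiolar epithelium (cm/s).
#' @param Papp_alveolar Apparent permeability, alveolar epithelium (cm/s).
#' @param density Particle density (g/mL).
#' @param B2P Blood-to-plasma concentration ratio.
#' @param Fup Fraction unbound in plasma.
#' @param diffusion_coeff Aqueous diffusion coefficient (cm^2/s).
#' @return List of class `drug_params`.
#' @export
drug_params <- function(MW = 239.32, logP = 0.74, pKa = c(10.61, 9.35),
                        ref_solubility = 270, lung_solubility = 384.70,
                        Papp_bronchiolar = 8.53e-7, Papp_alveolar = 1.59e-5,
                        density = 1.33, B2P = 0.96, Fup = 0.92,
                        diffusion_coeff = 0.80e-5) {
  stopifnot(MW > 0, ref_solubility > 0, lung_solubility > 0,
            Papp_bronchiolar > 0, Papp_alveolar > 0, density > 0,
            B2P > 0, B2P <= 2, Fup > 0, Fup <= 1, diffusion_coeff > 0)
  structure(as.list(environment()), class = "drug_params")
}

#' Lung disposition parameters
#'
#' Regional lining-fluid volumes, effective absorptive surface areas,
#' unbound-to-cells fractions and mucociliary transfer rates of the
#' pulmonary absorption model, plus the extra-thoracic fate split.
#' The fate split and unbound fractions are the fitted values of the
#' inhalation model (65% of extra-thoracic drug swallowed, 30% expectorated,
#' 15%/20% unbound in alveolar/extra-thoracic cells, first-pass extraction
#' 100%); lining volumes, effective areas and transfer rates are bundled
#' defaults calibrated so the reference product simulation reproduces its
#' observed plasma pharmacokinetics (methods vignette).
#'
#' @param fu_alveolar Fraction of dissolved drug unbound in the alveolar
#'   compartment and available for permeation.
#' @param fu_ET Same, extra-thoracic compartment.
#' @param fu_TB Same, tracheobronchial compartment.
#' @param swallowed_frac_ET Fraction of extra-thoracic deposit swallowed.
#' @param expectorated_frac_ET Fraction of extra-thoracic deposit expectorated.
#' @param first_pass_extraction Hepatic first-pass extraction of swallowed
#'   drug (1 = complete presystemic loss, the charcoal-block assumption).
#' @param sa_ET,sa_TB,sa_AL Effective absorptive surface areas (cm^2).
#' @param v_ET,v_TB,v_AL Lining-fluid volumes (mL).
#' @param k_mcc_TB Mucociliary transfer rate, tracheobronchial to
#'   extra-thoracic (1/h).
#' @param k_mcc_ET Transfer rate, extra-thoracic lining to gut (1/h).
#' @return List of class `lung_disposition_params`.
#' @export
lung_disposition_params <- function(fu_alveolar = 0.15, fu_ET = 0.20,
                                    fu_TB = 1.0,
                                    swallowed_frac_ET = 0.65,
                                    expectorated_frac_ET = 0.30,
                                    first_pass_extraction = 1.0,
                                    sa_ET = 1500, sa_TB = 2400, sa_AL = 15000,
                                    v_ET = 1.2, v_TB = 5, v_AL = 15,
                                    k_mcc_TB = 0.4, k_mcc_ET = 0.1) {
  stopifnot(swallowed_frac_ET + expectorated_frac_ET <= 1,
            swallowed_frac_ET >= 0, expectorated_frac_ET >= 0,
            first_pass_extraction >= 0, first_pass_extraction <= 1,
            fu_alveolar > 0, fu_alveolar <= 1, fu_ET > 0, fu_ET <= 1,
            fu_TB > 0, fu_TB <= 1,
            sa_ET > 0, sa_TB > 0, sa_AL > 0, v_ET > 0, v_TB > 0, v_AL > 0,
            k_mcc_TB >= 0, k_mcc_ET >= 0)
  structure(as.list(environment()), class = "lung_disposition_params")
}

#' Systemic (whole-body) parameters
#'
#' @param body_weight Body weight (kg).
#' @param CL_renal Renal plasma clearance (mL/min/kg).
#' @param CL_hepatic Hepatic plasma clearance (mL/min/kg).
#' @param plasma_volume Total plasma volume (L).
#' @param cardiac_output_blood Cardiac output, blood (L/h).
#' @param hematocrit Hematocrit fraction.
#' @param lung_tissue_volume Lung tissue volume (L).
#' @param physiology Data frame of tissue volumes and flow fractions; the
#'   bundled 77 kg reference table by default.
#' @return List of class `systemic_params`.
#' @export
systemic_params <- function(body_weight = 77, CL_renal = 4.2,
                            CL_hepatic = 5.44, plasma_volume = 3.78,
                            cardiac_output_blood = 348, hematocrit = 0.45,
                            lung_tissue_volume = 0.53,
                            physiology = NULL) {
  if (is.null(physiology)) {
    path <- system.file("extdata", "tissue_physiology_77kg.csv",
                        package = "dpipk")
    physiology <- utils::read.csv(path, comment.char = "#")
  }
  stopifnot(body_weight > 0, CL_renal >= 0, CL_hepatic >= 0,
            plasma_volume > 0, cardiac_output_blood > 0,
            hematocrit > 0, hematocrit < 1,
            abs(sum(physiology$flow_frac_co) - 1) < 1e-9)
  structure(as.list(environment()), class = "systemic_params")
}

#' Read a key=value PBPK configuration file
#'
#' Parses the plain-text configuration dialect shipped as
#' `extdata/salbutamol_diskus.cfg` (one `key = value` pair per line, `#`
#' comments, numeric vectors comma-separated) and builds the three parameter
#' sets.
#'
#' @param path Configuration file path; default is the bundled salbutamol
#'   set.
#' @return List with `drug`, `lung`, `systemic` parameter objects and `dose_ug`.
#' @export
read_pbpk_config <- function(path = system.file("extdata",
                                                "salbutamol_diskus.cfg",
                                                package = "dpipk")) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(trimws(strsplit(x[2], ",")[[1]]))),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  pick <- function(fn, prefix) {
    fml <- names(formals(fn))
    args <- vals[paste0(prefix, fml)]
    names(args) <- fml
    do.call(fn, args[!vapply(args, is.null, logical(1))])
  }
  list(drug = pick(drug_params, "drug."),
       lung = pick(lung_disposition_params, "lung."),
       systemic = pick(systemic_params, "sys."),
       dose_ug = vals[["dose_ug"]])
}
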