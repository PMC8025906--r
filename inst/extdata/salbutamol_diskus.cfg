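# Inhaled salbutamol sulphate, reference (Diskus-type) parameter set.
# Units: MW g/mol; solubilities mg/mL; permeabilities cm/s; density g/mL;
# diffusion coefficient cm^2/s; clearances mL/min/kg; plasma volume L;
# cardiac output L/h (blood); surface areas cm^2; lining volumes mL;
# mucociliary rates 1/h; dose ug.

dose_ug = 600

# --- drug ---
drug.MW = 239.32
drug.logP = 0.74
drug.pKa = 10.61, 9.35          # diprotic base convention
drug.ref_solubility = 270.00    # pH 7.4
drug.lung_solubility = 384.70   # simulated lung fluid
drug.Papp_bronchiolar = 8.53e-7
drug.Papp_alveolar = 1.59e-5
drug.density = 1.33
drug.B2P = 0.96
drug.Fup = 0.92
drug.diffusion_coeff = 0.80e-5

# --- lung disposition ---
lung.fu_alveolar = 0.15
lung.fu_ET = 0.20
lung.fu_TB = 1.0
lung.swallowed_frac_ET = 0.65
lung.expectorated_frac_ET = 0.30
lung.first_pass_extraction = 1.0
# effective absorptive areas and lining volumes (bundled physiology defaults,
# calibrated against the reference-product plasma profile; see vignette)
lung.sa_ET = 1500
lung.sa_TB = 2400
lung.sa_AL = 15000
lung.v_ET = 1.2
lung.v_TB = 5
lung.v_AL = 15
lung.k_mcc_TB = 0.4
lung.k_mcc_ET = 0.1

# --- systemic ---
sys.body_weight = 77
sys.CL_renal = 4.2
sys.CL_hepatic = 5.44
sys.plasma_volume = 3.78
sys.cardiac_output_blood = 348
sys.hematocrit = 0.45
sys.lung_tissue_volume = 0.53
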