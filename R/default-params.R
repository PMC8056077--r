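#' Calibrated default parameter values
#'
#' The reference parameter set for [build_default_model()], obtained by the
#' package's rough-tuning procedure: rate constants solved from a
#' stoichiometrically consistent mid-filling flux plan at the actual enzyme
#' levels, with affinity and inhibition constants placed at the planned
#' operating pools, then adjusted against the physiological read-outs
#' (storage-product time courses, flux ratios, FA turnover) and the
#' perturbation-response panel.
#'
#' @return Named numeric vector of kinetic parameters.
#' @export
default_parameter_values <- function() {
  c(
    alpha_ATPM = 4,
    beta_ATPM = 0.03,
    k_AAT = 0.06672495642,
    k_AAup = 0.07189954488,
    k_ACCc = 0.034163627,
    k_ACCp = 0.2375236502,
    k_ACL = 0.008111900937,
    k_AKGD = 0.06100567444,
    k_CWI = 0.05120799745,
    k_EPI = 0.03840862186,
    k_FAE = 0.002640817295,
    k_FAS = 0.07605795647,
    k_FAT = 0.008878760844,
    k_G6PD = 0.06873720771,
    k_GDH = 0.02334400808,
    k_GLCT = 0.1557430281,
    k_HK = 0.2423985655,
    k_ICL = 0.007205321593,
    k_IDH = 0.04668801616,
    k_LEAK = 0.3493333333,
    k_MDH = 0.01847221509,
    k_ME = 0.01906427326,
    k_NPG = 0.01593246536,
    k_OX = 0.03428571429,
    k_OXPHOS = 0.3954474968,
    k_PDH = 0.3781729309,
    k_PDHp = 0.388974522,
    k_PEPC = 0.1021300353,
    k_PEPT = 0.5223572573,
    k_PFK = 0.1626559045,
    k_PGK = 0.1978812198,
    k_PKc = 0.06333154982,
    k_PKp = 0.3345817726,
    k_PYRT = 0.01638767866,
    k_RUB = 0.09331734192,
    k_SPRTS = 0.0006,
    k_STAD = 0.009598660372,
    k_STAS = 0.1170361131,
    k_SUS = 0.001,
    k_TAGD = 0.001668280798,
    k_TAGS = 0.002138879089,
    Keq_MDH = 1,
    Keq_PEPT = 5,
    Keq_SUS = 2,
    Ki_AAup_ALA = 0.3,
    Ki_ACCc_MCA_c = 0.5,
    Ki_ACCp_MACP = 0.2,
    Ki_CWI_HEX_a = 0.05,
    Ki_FAT_FA = 0.25,
    Ki_GLCT_GLC = 0.08,
    Ki_HK_HP_c = 0.03,
    Ki_PDHp_ACA_p = 0.06,
    Ki_PFK_PEP_c = 0.05,
    Ki_PKp_PYR_p = 0.05,
    Ki_SCFA = 0.1,
    Km_AAT_AKG = 0.2,
    Km_AAT_ALA = 0.3,
    Km_AAup_AA_e = 0.3,
    Km_ACCc_ACA_c = 1,
    Km_ACCp_ACA_p = 0.1,
    Km_ACL_CIT = 0.3,
    Km_AKGD_ADP = 0.1,
    Km_AKGD_AKG = 0.2,
    Km_ATP = 0.1,
    Km_ATPM_ATP = 0.3,
    Km_CWI_SUC_e = 0.5,
    Km_EPI_R5P = 0.1,
    Km_FAE_FA = 0.01,
    Km_FAE_MCA_c = 0.3,
    Km_FAE_NADPH = 0.02,
    Km_FAS_ACA_p = 0.1,
    Km_FAS_MACP = 0.1,
    Km_FAS_NADH = 0.1,
    Km_FAS_NADPH = 0.1,
    Km_FAT_SCFA = 0.1,
    Km_G6PD_HP_c = 0.01,
    Km_G6PD_NADP = 0.3,
    Km_GDH_GLU = 0.3,
    Km_GLCT_HEX_a = 0.001,
    Km_HK_GLC = 0.3,
    Km_ICL_ACA_c = 0.2,
    Km_IDH_CIT = 0.3,
    Km_LEAK_NADH = 0.1,
    Km_MDH_MAL = 0.3,
    Km_MDH_NAD = 0.1,
    Km_MDH_NADH = 0.1,
    Km_MDH_OAA = 0.1,
    Km_ME_MAL = 0.3,
    Km_ME_NADP = 0.1,
    Km_NAD = 0.1,
    Km_NPG_NADP = 0.1,
    Km_NPG_TP_c = 0.2,
    Km_OX_NADPH = 0.1,
    Km_OXPHOS_ADP = 0.3,
    Km_OXPHOS_NADH = 0.1,
    Km_PDH_OAA = 0.1,
    Km_PDH_PYR_c = 0.2,
    Km_PDHp_PYR_p = 0.1,
    Km_PEPC_PEP_c = 0.2,
    Km_PEPT_PEP_c = 0.2,
    Km_PEPT_PEP_p = 0.2,
    Km_PFK_HP_c = 0.1,
    Km_PGK_ADP = 0.1,
    Km_PGK_TP_c = 0.2,
    Km_PKc_ADP = 0.1,
    Km_PKc_PEP_c = 0.2,
    Km_PKp_ADP = 0.1,
    Km_PKp_PEP_p = 0.2,
    Km_PYRT_PYR_c = 0.3,
    Km_RUB_R5P = 0.3,
    Km_SPRTS_ALA = 0.2,
    Km_SPRTS_GLU = 0.2,
    Km_STAD_STA = 0.5,
    Km_STAS_HP_c = 0.1,
    Km_SUS_GLC = 0.5,
    Km_SUS_SUC = 1,
    Km_TAGD_TAG = 1,
    Km_TAGS_FA = 0.5,
    n_AAup = 2,
    n_ACCc = 2,
    n_ACCp = 2,
    n_CWI = 2,
    n_FAT = 3,
    n_GLCT = 2,
    n_HK = 2,
    n_PDHp = 2,
    n_PFK = 2,
    n_PKp = 2,
    n_SCFA = 2
  )
}
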