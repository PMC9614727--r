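## Physical constants and unit conversions (internal units: nm, ns, kJ/mol).

#' Physical constants used by poreflux
#'
#' @format A named list:
#' \describe{
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{R}{Molar gas constant, J mol^-1 K^-1.}
#'   \item{kJmol_per_MPa_nm3}{Energy of 1 MPa x 1 nm^3 expressed in kJ/mol.}
#'   \item{pN_per_kJmol_nm}{1 kJ mol^-1 nm^-1 expressed in piconewton.}
#'   \item{v_W}{Default average volume of one water molecule, nm^3
#'     (bulk water at 300 K, 1 bar).}
#'   \item{V_W}{Default molar volume of water, cm^3 mol^-1.}
#' }
#' @export
pf_constants <- local({
  N_A <- 6.02214076e23
  list(
    N_A = N_A,
    R = 8.314462618,
    # 1 MPa * 1 nm^3 = 1e6 J/m^3 * 1e-27 m^3 = 1e-21 J; per mol, in kJ:
    kJmol_per_MPa_nm3 = 1e-21 * N_A / 1e3,
    # 1 kJ/mol/nm = 1e3 J / N_A / 1e-9 m, in pN (1e-12 N):
    pN_per_kJmol_nm = 1e3 / N_A / 1e-9 / 1e-12,
    v_W = 0.0301,
    V_W = 18.07
  )
})

## 1 nm/ns == 1 m/s; 1 (nm/ns)/MPa == 1e-6 m Pa^-1 s^-1.
## 1 cm^5 N^-1 s^-1 == 1e-10 m^3 Pa^-1 s^-1.
## slope[(nm/ns)/MPa] * A[nm^2] -> 1e-24 m^3/Pa/s == 1e-14 cm^5 N^-1 s^-1.
.CM5_PER_SLOPE_AREA <- 1e-14
.CM_S_PER_NM_NS <- 100
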