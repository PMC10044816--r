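#' Ligament bundle registry of the intact knee
#'
#' Nineteen ligament and capsular bundles with normalised stiffness K (N),
#' zero-load length L0 (mm) and reference strain eps_r (strain at the
#' full-extension reference pose).  Bundles: two-bundle ACL (aACL, pACL),
#' two-bundle PCL (aPCL, pPCL), three superficial MCL bundles (aMCL, iMCL,
#' pMCL), two deep MCL bundles (aDMCL, pDMCL), LCL, POPL, ALL, four posterior
#' capsule bundles (CAPa, CAPo, CAPm, CAPl) and three patellar tendon bundles
#' (cPT, mPT, lPT).  The patellar-tendon bundles are carried in the registry
#' but mechanically inactive: there is no patella body and passive flexion
#' involves no quadriceps force.
#'
#' @param eps_l transition strain of the toe region (dimensionless).
#' @param damping_c linear damping coefficient, N s/mm; inactive in
#'   quasi-static solves and kept only for completeness.
#' @return data.frame with columns `name`, `K_N`, `L0_mm`, `eps_r`, `eps_l`,
#'   `damping_c`, `group`, `active`.
#' @export
default_bundle_registry <- function(eps_l = 0.03, damping_c = 0.5) {
  reg <- data.frame(
    name = c("aACL", "pACL", "aPCL", "pPCL",
             "aMCL", "iMCL", "pMCL", "aDMCL", "pDMCL",
             "LCL", "POPL", "ALL",
             "CAPa", "CAPo", "CAPm", "CAPl",
             "cPT", "mPT", "lPT"),
    K_N = c(3600, 4000, 4000, 1600,
            2000, 2000, 4000, 2000, 1800,
            3400, 1900, 2700,
            1350, 1500, 2000, 2000,
            6000, 6000, 6000),
    L0_mm = c(32, 34, 34, 32,
              85, 85, 56, 58, 57,
              49, 45, 43,
              45, 43, 28, 27,
              48, 47, 45),
    eps_r = c(0.03, 0.03, -0.05, -0.06,
              0.02, 0.03, 0.05, 0.02, 0.05,
              0.05, -0.05, 0.05,
              0.05, 0.05, 0.05, 0.05,
              0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  reg$eps_l <- eps_l
  reg$damping_c <- damping_c
  reg$group <- c("ACL", "ACL", "PCL", "PCL",
                 "MCL", "MCL", "MCL", "DMCL", "DMCL",
                 "LCL", "POPL", "ALL",
                 "CAP", "CAP", "CAP", "CAP",
                 "PT", "PT", "PT")
  reg$active <- reg$group != "PT"
  reg
}

validate_registry <- function(reg) {
  need <- c("name", "K_N", "L0_mm", "eps_r")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("ligament registry is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop("ligament registry has duplicated bundle names")
  if (any(reg$K_N <= 0)) stop("ligament registry: K must be > 0")
  if (any(reg$L0_mm <= 0)) stop("ligament registry: L0 must be > 0")
  if (any(reg$eps_r <= -1)) stop("ligament registry: eps_r must be > -1")
  invisible(reg)
}

#' Read / write a ligament registry file
#'
#' CSV with columns `name,K_N,L0_mm,eps_r` (additional columns `eps_l`,
#' `damping_c`, `group`, `active` are preserved if present; defaults are
#' filled otherwise).  The schema is validated strictly.
#'
#' @param path file path.
#' @return `read_registry`: validated registry data.frame.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
  def <- default_bundle_registry()
  if (is.null(reg$eps_l)) reg$eps_l <- def$eps_l[1]
  if (is.null(reg$damping_c)) reg$damping_c <- def$damping_c[1]
  if (is.null(reg$group)) reg$group <- def$group[match(reg$name, def$name)]
  if (is.null(reg$active)) reg$active <- def$active[match(reg$name, def$name)]
  reg
}

#' @rdname read_registry
#' @param reg a registry data.frame.
#' @export
write_registry <- function(reg, path) {
  validate_registry(reg)
  utils::write.csv(reg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle strain from current and zero-load length
#'
#' Engineering strain `(length - L0)/L0`; negative values indicate a slack
#' bundle (which carries no force).
#'
#' @param length current path length, mm.
#' @param L0 zero-load (slack) length, mm; must be > 0.
#' @return strain (dimensionless), vectorised.
#' @export
bundle_strain <- function(length, L0) {
  if (any(L0 <= 0)) stop("bundle_strain: L0 must be > 0")
  (length - L0) / L0
}

#' Nonlinear bundle force law (quadratic toe, linear region)
#'
#' Tension is zero for non-positive strain, `K * strain^2 / (4 eps_l)` in the
#' toe region `0 < strain <= 2 eps_l`, and `K * (strain - eps_l)` beyond.
#' The two branches agree at the transition strain `2 eps_l` and the law is
#' continuous and monotone non-decreasing.
#'
#' @param strain engineering strain (may be negative).
#' @param K normalised stiffness, N.
#' @param eps_l transition strain (default 0.03).
#' @return tension in N, vectorised over `strain`.
#' @export
#' @examples
#' bundle_force(0.06, K = 3600)   # 108 N at the branch transition
bundle_force <- function(strain, K, eps_l = 0.03) {
  if (any(K <= 0)) stop("bundle_force: K must be > 0")
  if (any(eps_l <= 0)) stop("bundle_force: eps_l must be > 0")
  toe <- K * strain^2 / (4 * eps_l)
  lin <- K * (strain - eps_l)
  ifelse(strain <= 0, 0, ifelse(strain <= 2 * eps_l, toe, lin))
}

#' Elastic energy stored in a bundle, per the toe/linear force law
#'
#' Integral of tension over elongation; used by the equilibrium solver, whose
#' equilibria are stationary points of the total potential.
#'
#' @inheritParams bundle_force
#' @param L0 zero-load length, mm (energy scales with L0 because strain is
#'   normalised by it).
#' @return energy in N mm, vectorised.
#' @keywords internal
bundle_energy <- function(strain, K, L0, eps_l = 0.03) {
  toe <- K * strain^3 / (12 * eps_l)
  e2 <- 2 * eps_l
  lin <- K * e2^3 / (12 * eps_l) +
    K * ((strain - eps_l)^2 - eps_l^2) / 2
  L0 * ifelse(strain <= 0, 0, ifelse(strain <= e2, toe, lin))
}

#' Zero-load length from a reference length and reference strain
#'
#' Inverts the attachment-calibration rule `L_ref = L0 (1 + eps_r)`.
#'
#' @param L_ref bundle path length at the reference (full extension) pose, mm.
#' @param eps_r reference strain; must be > -1.
#' @return L0 in mm.
#' @export
slack_from_reference <- function(L_ref, eps_r) {
  if (any(eps_r <= -1)) stop("slack_from_reference: eps_r must be > -1")
  L_ref / (1 + eps_r)
}
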