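#' Deterministic synthetic fixtures for oracle tests
#'
#' Writes small, fully synthetic inputs with known closed-form properties,
#' used by the test oracles:
#' \describe{
#'   \item{flat-landscape}{TSV landscape with F = 0 over 0-300 nm.}
#'   \item{double-well}{TSV landscape F = 2*cos(2*pi*Rx/125.66) kBT; minima
#'     spaced 125.66 nm apart.}
#'   \item{tiny-chain-N2}{YAML parameter set for a 2-subunit chain whose
#'     Boltzmann marginals are computable by quadrature over one angle.}
#'   \item{tiny-chain-N3}{Same, 3 subunits (two movable angles).}
#'   \item{square-wave-traj}{TSV trajectory with Rx a 2 s-period square wave
#'     alternating 0/50 nm (Tu = 1 s, Nu = 0.5/s at a 10 nm threshold).}
#' }
#'
#' @param name One of the fixture names above.
#' @param dir Output directory.
#' @return Path of the written file.
#' @export
make_fixture <- function(name, dir = tempdir()) {
  known <- c("flat-landscape", "double-well", "tiny-chain-N2",
             "tiny-chain-N3", "square-wave-traj")
  if (!name %in% known)
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(known, collapse = ", ")))
  path <- file.path(dir, paste0(name, if (grepl("tiny", name)) ".yaml" else ".tsv"))
  if (name == "flat-landscape") {
    write_landscape_tsv(landscape(seq(0, 300, 2), rep(0, 151)), path)
  } else if (name == "double-well") {
    x <- seq(0, 300, 1)
    write_landscape_tsv(landscape(x, 2 * cos(2 * pi * x / 125.66)), path)
  } else if (name == "square-wave-traj") {
    t <- seq(0, 10, 0.01)
    rx <- ifelse(t %% 2 < 1, 50, 0)
    utils::write.table(data.frame(t_s = t, Rx_nm = rx), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    n <- if (name == "tiny-chain-N2") 2L else 3L
    yaml::write_yaml(list(model = list(b_nm = 8, n_subunits = n, l0_nm = 6.5,
                                       lmax_over_l0 = 1.2, E_ms_kBT = 2,
                                       E_mb_kBT = 1, theta_D_rad = 0.4,
                                       theta_T_rad = 0, cap_T_subunits = 0)),
                     path)
  }
  path
}
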