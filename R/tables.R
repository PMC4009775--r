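#' Reference MD-study tables for the A3Gctd NMR/crystal comparison
#'
#' Published per-run values from 20-ns explicit-solvent MD simulations of
#' the A3Gctd NMR (2KEM) and crystal (3IR2) structures, shipped as plain
#' CSV: main-chain RMSD and zinc ligand-water counts after 10 and 20 ns
#' (ten independent runs each), main-chain RMSD of three DNA-binding
#' arginines, and the replicate free-energy table (G2, printed -TS, G1 per
#' run and form). These serve as inputs for the table-arithmetic
#' validations: recombining G1 = G2 + (-TS) row-wise and recomputing
#' column means and replicate statistics with the package's own
#' aggregation functions.
#'
#' @return named list of data.frames: \code{rmsd_10ns}, \code{rmsd_20ns},
#'   \code{arg_rmsd_20ns}, \code{free_energy_runs}
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "confree",
                                  mustWork = TRUE)
  list(
    rmsd_10ns = utils::read.csv(path("a3gctd_rmsd_10ns.csv")),
    rmsd_20ns = utils::read.csv(path("a3gctd_rmsd_20ns.csv")),
    arg_rmsd_20ns = utils::read.csv(path("a3gctd_arg_rmsd_20ns.csv")),
    free_energy_runs = utils::read.csv(path("a3gctd_free_energy_runs.csv")))
}

#' Build free-energy records from a published G2 / -TS table
#'
#' The printed table stores the entropy column as \code{-TS} (negative
#' values; G1 = G2 + printed column). Records are reconstructed with the
#' package convention TS = -printed value, so \code{g1 = g2 - ts}
#' reproduces the printed G1 column.
#'
#' @param df data.frame with columns \code{form}, \code{run}, \code{g2},
#'   \code{ts_printed}
#' @param form which form to extract (a value of \code{df$form})
#' @return list of \code{free_energy_record}s
#' @export
records_from_table <- function(df, form) {
  d <- df[df$form == form, , drop = FALSE]
  if (!nrow(d)) stop("form '", form, "' not present in table")
  lapply(seq_len(nrow(d)), function(k)
    free_energy_record(label = form, run = d$run[k],
                       e_mm = d$g2[k], e_asa = 0,
                       s = -d$ts_printed[k] / (KB_KCALMOL * 300),
                       ts = -d$ts_printed[k]))
}
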