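#' @useDynLib phasefus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot median setNames runif
#' @importFrom utils head tail write.csv
NULL

# molar concentration of a species at 1 molecule per nm^3
.MOLAR_PER_NM3 <- 1e24 / 6.02214076e23

#' Define a multivalent sticker-and-spacer protein
#'
#' A chain of `N1` residues carrying `m1` tyrosine and `m2` arginine
#' stickers.  Tyr and Arg form reversible one-to-one cross-links; every
#' other residue is a spacer contributing only mixing entropy.
#'
#' @param N1 residues per chain.
#' @param m1 number of Tyr stickers per chain.
#' @param m2 number of Arg stickers per chain.
#' @return An object of class `protein_spec`.
#' @examples
#' fus <- protein_spec(526, 34, 34)
#' @export
protein_spec <- function(N1, m1, m2) {
  stopifnot(length(N1) == 1, length(m1) == 1, length(m2) == 1)
  N1 <- as.integer(N1); m1 <- as.integer(m1); m2 <- as.integer(m2)
  if (N1 < 1) stop("N1 must be >= 1")
  if (m1 < 0 || m2 < 0) stop("sticker counts must be >= 0")
  if (m1 + m2 > N1) stop("m1 + m2 cannot exceed the chain length N1")
  structure(list(N1 = N1, m1 = m1, m2 = m2), class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> N1 = %d residues, m1 = %d Tyr, m2 = %d Arg\n",
              x$N1, x$m1, x$m2))
  invisible(x)
}

#' Default per-bond ATP-Arg binding free energy for a given ATP valence
#'
#' For di- and trivalent ATP the per-bond average is anchored to the
#' quantum-chemistry result that ATP-Arg binding is nearly four times
#' as strong as the Tyr-Arg bond (-8 kT against -2 kT).  The
#' monovalent case is a full Arg-triphosphate salt bridge, much
#' stronger per bond than the shared multivalent arrangements (the
#' per-bond average weakens as more arginines crowd one triphosphate);
#' its default is calibrated so the monovalent dissolution
#' concentration reproduces the micromolar scale of the reference
#' phase diagrams (see the methods vignette).
#'
#' @param L ATP valence (1, 2 or 3).
#' @return Per-bond binding free energy in units of kT (negative =
#'   favorable).  Override via the `beta_eps2` argument of
#'   [model_params()] when other estimates are available.
#' @export
default_beta_eps2 <- function(L) {
  stopifnot(L %in% 1:3)
  c(`1` = -12.5, `2` = -8, `3` = -8)[[as.character(L)]]
}

#' Assemble the full mean-field parameter set
#'
#' @param protein a [protein_spec()].
#' @param N2 solvent chain length (the single fit parameter of the
#'   ATP-free model; 65 reproduces a 5 uM FUS saturation concentration).
#' @param beta_eps1 Tyr-Arg binding free energy in kT (negative =
#'   favorable).
#' @param L ATP valence: how many Arg one ATP can bind (1-3).
#' @param beta_eps2 per-bond ATP-Arg binding free energy in kT; default
#'   taken from [default_beta_eps2()] for the given `L`.
#' @param chi Flory interaction between ATP and solvent (ATP is strongly
#'   hydrated, hence the negative default).
#' @param atp_reservoir_phi volume fraction of ATP in the reservoir the
#'   solution exchanges with; 0 switches the ATP machinery off.
#' @param residue_size_nm hydration radius of one residue (nm); the
#'   unit volume v = (4/3) pi residue_size_nm^3 fixes all
#'   concentration conversions.
#' @return An object of class `model_params`.
#' @examples
#' pars <- model_params(protein_spec(526, 34, 34))
#' @export
model_params <- function(protein,
                         N2 = 65,
                         beta_eps1 = -2,
                         L = 2,
                         beta_eps2 = default_beta_eps2(L),
                         chi = -1.2,
                         atp_reservoir_phi = 0,
                         residue_size_nm = 0.65) {
  stopifnot(inherits(protein, "protein_spec"))
  if (N2 < 1) stop("N2 must be >= 1")
  if (!(L %in% 1:3)) stop("ATP valence L must be 1, 2 or 3")
  if (atp_reservoir_phi < 0 || atp_reservoir_phi >= 1)
    stop("atp_reservoir_phi must lie in [0, 1)")
  if (residue_size_nm <= 0) stop("residue_size_nm must be positive")
  structure(list(protein = protein, N2 = N2,
                 beta_eps1 = beta_eps1, beta_eps2 = beta_eps2,
                 L = as.integer(L), chi = chi,
                 atp_reservoir_phi = atp_reservoir_phi,
                 residue_size_nm = residue_size_nm),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params> N1=%d m1=%d m2=%d | N2=%g | ",
                     "beta_eps1=%g beta_eps2=%g L=%d chi=%g | ",
                     "reservoir phi=%g\n"),
              x$protein$N1, x$protein$m1, x$protein$m2, x$N2,
              x$beta_eps1, x$beta_eps2, x$L, x$chi, x$atp_reservoir_phi))
  invisible(x)
}

#' Named parameter profiles
#'
#' `"fus2022"` is the symmetric FUS case (N1 = 526, m1 = m2 = 34,
#' N2 = 65, Tyr-Arg energy -2 kT, chi = -1.2).  `"asym_hiY"` and
#' `"asym_hiR"` are the prion-like asymmetric-sticker variants
#' (m1 = 34, m2 = 11 and m1 = 11, m2 = 34) with trivalent ATP.
#'
#' @param name profile name.
#' @param ... overrides forwarded to [model_params()].
#' @return A `model_params` object.
#' @examples
#' fus_profile("fus2022")
#' @export
fus_profile <- function(name = c("fus2022", "asym_hiY", "asym_hiR"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    fus2022  = protein_spec(526, 34, 34),
    asym_hiY = protein_spec(526, 34, 11),
    asym_hiR = protein_spec(526, 11, 34))
  defaults <- switch(name,
    fus2022  = list(L = 2),
    asym_hiY = list(L = 3),
    asym_hiR = list(L = 3))
  args <- utils::modifyList(defaults, list(...))
  do.call(model_params, c(list(protein = spec), args))
}

#' Convert a volume fraction to a molar concentration
#'
#' A species occupying volume fraction `phi`, made of
#' `n_beads_per_unit` residues, has molarity
#' `phi / (n_beads_per_unit * v * N_A)` where the per-residue volume
#' is the hydration sphere `v = (4/3) pi residue_size_nm^3`, with
#' `residue_size_nm` the residue hydration radius.  (The
#' spherical volume, not the cube of the size, is what makes the
#' theory's dilute-branch and dissolution concentrations land on the
#' experimental micromolar/millimolar scales; see the methods
#' vignette.)  For protein chains use `n_beads_per_unit = N1`; for
#' ATP use 1.
#'
#' @param phi volume fraction in \[0, 1\].
#' @param n_beads_per_unit residues per molecule.
#' @param residue_size_nm residue hydration radius in nm.
#' @return Concentration in mol/L.
#' @examples
#' phi_to_molar(1.8e-3, 526)  # about 5e-6 M
#' @export
phi_to_molar <- function(phi, n_beads_per_unit = 1, residue_size_nm = 0.65) {
  stopifnot(all(phi >= 0), all(phi <= 1))
  v <- 4 / 3 * pi * residue_size_nm^3
  phi / (n_beads_per_unit * v) * .MOLAR_PER_NM3
}

#' Convert a molar concentration to a volume fraction
#'
#' Inverse of [phi_to_molar()].
#'
#' @inheritParams phi_to_molar
#' @param molar concentration in mol/L.
#' @return Volume fraction.
#' @export
molar_to_phi <- function(molar, n_beads_per_unit = 1, residue_size_nm = 0.65) {
  stopifnot(all(molar >= 0))
  v <- 4 / 3 * pi * residue_size_nm^3
  molar * n_beads_per_unit * v / .MOLAR_PER_NM3
}

#' Count Tyr/Arg stickers in an amino-acid sequence
#'
#' @param sequence one-letter amino-acid string (20-letter alphabet
#'   plus X).
#' @param id optional sequence identifier used in error messages.
#' @return A [protein_spec()] with `N1 = nchar(sequence)`,
#'   `m1 = #Y`, `m2 = #R`.
#' @examples
#' sequence_to_spec("YRYG")
#' @export
sequence_to_spec <- function(sequence, id = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop(id, ": empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  ok <- chars %in% strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  if (!all(ok))
    stop(sprintf("%s: invalid residue '%s' at position %d",
                 id, chars[!ok][1], which(!ok)[1]))
  protein_spec(length(chars), sum(chars == "Y"), sum(chars == "R"))
}

#' Read protein specs from a FASTA file
#'
#' @param path FASTA file; each record becomes one [protein_spec()].
#' @return Named list of `protein_spec` objects.
#' @export
read_fasta_specs <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta_specs() requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    sequence_to_spec(as.character(seqs[[i]]), id = names(seqs)[i]))
  names(out) <- names(seqs)
  out
}

#' Generate a random sticker sequence
#'
#' Places Y and R stickers at the given per-type fraction (exact counts,
#' rounded) at random positions; all remaining residues are G.
#'
#' @param length chain length.
#' @param sticker_fraction per-type sticker fraction (each of Y and R).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return A list with `id` and `sequence`.
#' @examples
#' random_sticker_sequence(50, 0.06, seed = 1)
#' @export
random_sticker_sequence <- function(length, sticker_fraction = 0.06,
                                    seed = NULL) {
  stopifnot(length >= 1, sticker_fraction >= 0)
  n_each <- round(sticker_fraction * length)
  if (2 * n_each > length)
    stop("sticker fractions infeasible: 2*round(f*length) exceeds length")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  chars <- rep("G", length)
  pos <- sample.int(length, 2 * n_each)
  if (n_each > 0) {
    chars[pos[seq_len(n_each)]] <- "Y"
    chars[pos[n_each + seq_len(n_each)]] <- "R"
  }
  list(id = sprintf("random_L%d_f%g_s%s", length, sticker_fraction,
                    if (is.null(seed)) "NA" else seed),
       sequence = paste(chars, collapse = ""))
}
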