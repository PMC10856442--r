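# Protein sequences and oligomer model definitions.

#' Amylin (human IAPP) primary sequence
#'
#' The canonical 37-residue human islet amyloid polypeptide. Its key
#' hydrophobic residues C7, L16, I26 and V32 anchor the hydropathy profile
#' used throughout the binding-pattern analyses.
#'
#' @return one-letter amino-acid string of length 37.
#' @export
amylin_sequence <- function() {
  "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"
}

#' Synthetic 130-residue tau construct
#'
#' A SYNTHETIC stand-in for the 130-residue tau fragment used in the raft
#' binding models: a fixed polar background carrying hydrophobic anchor
#' patches centred at residues 6, 35, 66, 86, 112 and 121 (V6, I35, I66,
#' I86, I112, V121), reproducing the qualitative shape of tau's hydropathy
#' profile. It is not a transcript of any natural tau isoform and is intended
#' for synthetic fixtures only.
#'
#' @return one-letter amino-acid string of length 130.
#' @export
tau_sequence <- function() {
  paste0("RGQNLVFSRQKQQDNQTENATRHSRERGTPRHRLIFPRDENPSRKTKKTSQAEKPDPNAEQKAS",
         "LIFHNGGASGNRAEERAQQSLIFTANPNDTGPKDTDEQKKKAKPGRLIFEGSPSALVFAHGQPRQR")
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

aa_three_letter <- function(one) {
  idx <- match(strsplit(one, "")[[1L]], AA1)
  if (anyNA(idx)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(strsplit(one, "")[[1L]][is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  AA3[idx]
}

monomer_sequence <- function(monomer_type) {
  switch(monomer_type,
         tau = tau_sequence(),
         amylin = amylin_sequence(),
         stop("unknown monomer type: ", monomer_type, call. = FALSE))
}

#' Chain composition of an oligomer model
#'
#' Decodes model names of the campaign nomenclature: `1am`/`2am`/`4am`
#' (homo-amylin), `1tau`/`2tau`/`4tau` (homo-tau), and the hetero models
#' `1tam` (dimer: one tau + one amylin) and `2tam` (tetramer: two of each).
#' Hetero chain order follows the published layout (1tam: tau then amylin;
#' 2tam: amylin, tau, tau, amylin).
#'
#' @param model model name, e.g. `"2tam"`.
#' @return data.frame with `chain_id`, `monomer_type`, `sequence`, `length`.
#' @export
oligomer_chains <- function(model) {
  m <- regmatches(model, regexec("^([124])(tam|tau|am)$", model))[[1L]]
  if (length(m) == 0L) stop("unrecognised oligomer model: ", model,
                            call. = FALSE)
  n <- as.integer(m[2L])
  kind <- m[3L]
  types <- switch(kind,
                  am = rep("amylin", n),
                  tau = rep("tau", n),
                  tam = if (n == 1L) c("tau", "amylin")
                        else c("amylin", rep("tau", n), "amylin"))
  if (kind == "tam" && n > 2L) {
    stop("hetero models are limited to 1tam and 2tam", call. = FALSE)
  }
  seqs <- vapply(types, monomer_sequence, character(1))
  data.frame(chain_id = LETTERS[seq_along(types)],
             monomer_type = types,
             sequence = unname(seqs),
             length = nchar(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Total residue count of an oligomer model
#' @inheritParams oligomer_chains
#' @export
oligomer_residues <- function(model) sum(oligomer_chains(model)$length)
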