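#' Published oligonucleotide set for the tRiMetF31 / PFKFB3 system
#'
#' The printed sequences this package is exercised against: the 31-nt
#' 5' fragment of initiator methionine tRNA (tRiMetF31) in RNA and DNA
#' form, its scrambled control, the tRNA-iMet FISH detection probe, the
#' four luciferase-reporter cloning oligos for the PFKFB3 3'UTR site
#' (wild-type and deletion mutant, with XbaI/EcoRI sticky ends), the
#' poly(A)-tailed qPCR primers, and the two siRNA duplexes directed
#' against the fragment.
#'
#' @return Named character vector of uppercase sequences. RNA oligos use
#'   U, DNA oligos use T. Elements:
#'   \describe{
#'     \item{trf31_rna, trf31_dna}{WT-tRiMetF31, the 31-nt fragment.}
#'     \item{scr_rna}{Scr-tRiMetF31, scrambled negative control.}
#'     \item{fish_probe}{tRNA-iMet FISH probe (DNA, antisense to the
#'       tRNA, so its reverse complement is tRNA sequence).}
#'     \item{reporter_wt1, reporter_wt2}{Wild-type reporter oligo pair.}
#'     \item{reporter_mt1, reporter_mt2}{Deletion-mutant reporter pair
#'       (the predicted binding site removed).}
#'     \item{rtq_primer}{Anchored oligo(dT) reverse-transcription primer
#'       for poly(A)-tailed small RNA qPCR.}
#'     \item{timetf_sp}{tRiMetF31-specific forward qPCR primer.}
#'     \item{rtq_unir}{Universal reverse qPCR primer.}
#'     \item{sirna1_sense, sirna1_antisense, sirna2_sense,
#'       sirna2_antisense}{siRNA duplexes against tRiMetF31.}
#'   }
#' @examples
#' oligos <- trimet_sequences()
#' nchar(oligos[["trf31_rna"]]) # 31
#' @export
trimet_sequences <- function() {
  c(
    trf31_rna = "AGCAGAGUGGCGCAGCGGAAGCGUGCUGGGC",
    trf31_dna = "AGCAGAGTGGCGCAGCGGAAGCGTGCTGGGC",
    scr_rna   = "AUAUUACUGAUAACGUCAAUUCUAACAAUAA",
    fish_probe = "GGTTTCGATCCATCGACCTCTGGGTTATGGGC",
    reporter_wt1 = "CTAGACTTTTTTTTTTTCCTTTTCCAACCTGTTTCTTCCTCTCCCCCACTCTGCTTGAAAGACG",
    reporter_wt2 = "AATTCGTCTTTCAAGCAGAGTGGGGGAGAGGAAGAAACAGGTTGGAAAAGGAAAAAAAAAAAGT",
    reporter_mt1 = "CTAGACTTTTTTTTTTTCCTTTTCCAACCTGTTTCTTCCTCTCCCTTGAAAGACG",
    reporter_mt2 = "AATTCGTCTTTCAAGGGAGAGGAAGAAACAGGTTGGAAAAGGAAAAAAAAAAAGT",
    rtq_primer = "CGAATTCTAGAGCTCGAGGCAGGCGACATGGCTGGCTAGTTAAGCTTGGTACCGAGCTCGGATCCACTAGTCCTTTTTTTTTTTTTTTTTTTTTTTTGC",
    timetf_sp = "AAGCGTGCTGGGCAAAAA",
    rtq_unir  = "CGAATTCTAGAGCTCGAGGCAGG",
    sirna1_sense     = "AGAGUGGCGCAGCGGAAGCUU",
    sirna1_antisense = "GCUUCCGCUGCGCCACUCUUU",
    sirna2_sense     = "CAGAGUGGCGCAGCGGAAGUU",
    sirna2_antisense = "CUUCCGCUGCGCCACUCUGUU"
  )
}

#' Default 3' sequencing adapter
#'
#' The standard Illumina small-RNA 3' adapter used when trimming
#' read-through from 50-cycle single-end libraries.
#'
#' @return A 21-nt DNA string.
#' @export
default_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"
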