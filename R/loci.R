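#' The five SNaPshot age-marker loci and their base-channel chemistry
#'
#' After bisulfite conversion, an unmethylated cytosine reads as thymine
#' while a methylated cytosine stays cytosine. For assays whose extension
#' primer anneals to the converted top strand (ELOVL2, FHL2) the
#' methylated allele therefore incorporates C and the unmethylated allele
#' T; for bottom-strand assays (KLF14, C1orf132, TRIM59) the complementary
#' bases G and A are read instead. The returned table records, per locus,
#' which fluorescence channel carries the methylated and the unmethylated
#' allele, and a nominal fragment-size window used to pick the right peak
#' when an electropherogram contains several peaks in one channel.
#'
#' @param loci Optional character vector restricting the table to a subset
#'   of locus names.
#' @return A \code{data.frame} with columns \code{locus},
#'   \code{methylated_base}, \code{unmethylated_base}, \code{size_min},
#'   \code{size_max} (fragment sizes in nucleotides).
#' @examples
#' snapshotLoci()
#' snapshotLoci("ELOVL2")
#' @export
snapshotLoci <- function(loci = NULL) {
  def <- data.frame(
    locus = c("ELOVL2", "FHL2", "KLF14", "C1orf132", "TRIM59"),
    methylated_base = c("C", "C", "G", "G", "G"),
    unmethylated_base = c("T", "T", "A", "A", "A"),
    size_min = c(24, 32, 40, 48, 56),
    size_max = c(30, 38, 46, 54, 62),
    stringsAsFactors = FALSE
  )
  if (is.null(loci)) {
    return(def)
  }
  unknown <- setdiff(loci, def$locus)
  if (length(unknown) > 0L) {
    stop("unknown locus: ", paste(unknown, collapse = ", "))
  }
  def[match(loci, def$locus), , drop = FALSE]
}

#' Canonical locus order of the five-locus age model
#'
#' @return Character vector \code{c("ELOVL2", "FHL2", "KLF14", "C1orf132",
#'   "TRIM59")}, the order in which model coefficients are stored and
#'   profiles are laid out.
#' @examples
#' locusOrder()
#' @export
locusOrder <- function() {
  c("ELOVL2", "FHL2", "KLF14", "C1orf132", "TRIM59")
}
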