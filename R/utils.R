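#' Canonical variant identifier
#'
#' Joins chromosome, 1-based position, reference and alternate allele
#' into the identifier used to key variants throughout the pipeline.
#' Pure insertions/deletions use \code{"-"} for the empty allele.
#'
#' @param chrom chromosome name(s)
#' @param pos 1-based position(s)
#' @param ref reference allele(s)
#' @param alt alternate allele(s)
#' @return character vector \code{"chrom:pos:ref:alt"}
#' @examples
#' variantId("chr7", 140453136, "A", "T")
#' @export
variantId <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# en/em dashes occasionally used for empty indel alleles in tables
.canonicalAllele <- function(x) {
  x <- as.character(x)
  x[x %in% c("–", "—", "")] <- "-"
  x
}

# deterministic row order: subject, then chrom, pos, alt
.orderVariants <- function(v) {
  v[order(v$subject, v$chrom, v$pos, v$alt, method = "radix"), ,
    drop = FALSE]
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
}

# seeds derived from one master seed; kept within 32-bit integer range
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}

# atomic write: write to a temp file in the same directory, then rename
.writeAtomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}
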