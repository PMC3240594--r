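#' Construct a gene signature
#'
#' A signature is a named pair of gene sets: `up` genes (higher expression
#' when the represented entity is active) and `down` genes (lower). Derived
#' miRNA signatures come out of [derive_signature()]; curated pathway
#' signatures are typically read from GMT files.
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene symbols; stored as sets. The two
#'   components must be disjoint.
#' @param source One of `"derived_miRNA"` or `"curated_pathway"`.
#' @return An object of class `"gene_signature"`.
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           source = c("derived_miRNA", "curated_pathway")) {
  source <- match.arg(source)
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) {
    stop("up and down gene sets overlap for signature ", name)
  }
  structure(list(name = name, up = up, down = down, source = source),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d up, %d down\n",
              x$name, x$source, length(x$up), length(x$down)))
  invisible(x)
}

#' Signature size
#'
#' @param sig A gene signature.
#' @return `length(up) + length(down)`.
#' @export
signature_size <- function(sig) length(sig$up) + length(sig$down)

#' Read gene signatures from a GMT file
#'
#' Uses the Broad GMT dialect (name, description, then tab-separated genes).
#' A signed signature is stored as up to two lines named `NAME_UP` and
#' `NAME_DN`; a line without either suffix is read as an up-only signature.
#'
#' @param path Path to a GMT file.
#' @param source Source tag given to the parsed signatures.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, source = c("derived_miRNA", "curated_pathway")) {
  source <- match.arg(source)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character()))
  up <- list(); down <- list(); nms <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) stop("GMT line ", i, " has fewer than 2 fields")
    nm <- fields[1]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (grepl("_UP$", nm)) {
      up[[sub("_UP$", "", nm)]] <- genes
      nms <- c(nms, sub("_UP$", "", nm))
    } else if (grepl("_DN$", nm)) {
      down[[sub("_DN$", "", nm)]] <- genes
      nms <- c(nms, sub("_DN$", "", nm))
    } else {
      up[[nm]] <- genes
      nms <- c(nms, nm)
    }
  }
  nms <- unique(nms)
  sigs <- lapply(nms, function(nm) {
    gene_signature(nm, up = up[[nm]] %||% character(),
                   down = down[[nm]] %||% character(), source = source)
  })
  names(sigs) <- nms
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Each signature is written as a `NAME_UP` and/or `NAME_DN` line; empty
#' components are skipped. `read_gmt(write_gmt(x))` recovers `x` up to gene
#' set order.
#'
#' @param sigs A list of gene signatures.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sigs, path) {
  lines <- character()
  for (sig in sigs) {
    if (length(sig$up) > 0) {
      lines <- c(lines, paste(c(paste0(sig$name, "_UP"), sig$source, sig$up),
                              collapse = "\t"))
    }
    if (length(sig$down) > 0) {
      lines <- c(lines, paste(c(paste0(sig$name, "_DN"), sig$source, sig$down),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
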