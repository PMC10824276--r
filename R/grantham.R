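.otterpg_env <- new.env(parent = emptyenv())

#' The Grantham amino-acid distance matrix
#'
#' Returns the 20x20 physicochemical distance matrix of Grantham (1974),
#' bundled with the package as a plain-text table and validated for
#' symmetry and zero diagonal when first loaded. Row/column names are
#' one-letter amino-acid codes.
#'
#' @return a symmetric integer matrix
#' @export
grantham_matrix <- function() {
  if (is.null(.otterpg_env$grantham)) {
    path <- system.file("extdata", "grantham.tsv", package = "otterpg")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "integer"
    if (!isSymmetric(m) || any(diag(m) != 0))
      stop("bundled Grantham matrix failed validation")
    .otterpg_env$grantham <- m
  }
  .otterpg_env$grantham
}

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 one-letter amino-acid codes (vectorized)
#' @return integer score(s); an unknown code (including stop, `*`) is a
#'   lookup error
#' @export
grantham_score <- function(aa1, aa2) {
  m <- grantham_matrix()
  bad <- !(aa1 %in% rownames(m)) | !(aa2 %in% rownames(m))
  if (any(bad))
    stop("unknown amino-acid pair: ",
         paste(unique(paste0(aa1[bad], "/", aa2[bad])), collapse = ", "))
  m[cbind(aa1, aa2)]
}

#' Classify a Grantham score
#'
#' Following the convention of Chun and Fay (2009): conservative for
#' scores 0-50, moderate for 51-100, radical above 100. Moderate and
#' radical changes are flagged as putatively deleterious (score > 50).
#'
#' @param score integer Grantham score(s)
#' @return character vector in `{"conservative", "moderate", "radical"}`
#' @export
grantham_classify <- function(score) {
  stopifnot(all(score >= 0))
  ifelse(score > 100, "radical",
         ifelse(score > 50, "moderate", "conservative"))
}

#' Is a Grantham score putatively deleterious?
#' @param score integer Grantham score(s)
#' @return logical: `TRUE` for moderate or radical changes (score > 50)
#' @export
grantham_deleterious <- function(score) score > 50
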