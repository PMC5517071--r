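# The thirteen catalogued epistasis conditions. Each is defined by four
# genotypes g0 < g1 < g2 < g3 (lexicographic) satisfying g0 - g1 - g2 + g3 = 0,
# with interaction condition Delta_g1 * Delta_g2 != Delta_g0 * Delta_g3.
# Conditional types (a-f) fix one gene across the quadruple; marginal types
# (g-l) do not. Higher-order types derivable as sums of these are not included.
.catalog <- list(
  pairwise = list(quadruple = c("00", "01", "10", "11"), family = "pairwise"),
  a = list(quadruple = c("000", "010", "100", "110"), family = "conditional"),
  b = list(quadruple = c("001", "011", "101", "111"), family = "conditional"),
  c = list(quadruple = c("000", "001", "100", "101"), family = "conditional"),
  d = list(quadruple = c("010", "011", "110", "111"), family = "conditional"),
  e = list(quadruple = c("000", "001", "010", "011"), family = "conditional"),
  f = list(quadruple = c("100", "101", "110", "111"), family = "conditional"),
  g = list(quadruple = c("000", "011", "100", "111"), family = "marginal"),
  h = list(quadruple = c("001", "010", "101", "110"), family = "marginal"),
  i = list(quadruple = c("000", "010", "101", "111"), family = "marginal"),
  j = list(quadruple = c("001", "011", "100", "110"), family = "marginal"),
  k = list(quadruple = c("000", "001", "110", "111"), family = "marginal"),
  l = list(quadruple = c("010", "011", "100", "101"), family = "marginal")
)

#' Catalog of epistasis types
#'
#' Thirteen epistasis conditions are supported: the pairwise interaction,
#' six conditional triple types (`a`-`f`; a pairwise interaction given a fixed
#' mutation state of the remaining gene) and six marginal triple types
#' (`g`-`l`). Each type is an ordered quadruple of genotypes
#' \eqn{g_0 < g_1 < g_2 < g_3}; the null hypothesis of no epistasis is
#' \eqn{\Delta_{g_0}\Delta_{g_3} = \Delta_{g_1}\Delta_{g_2}} in tumor
#' fitness, and the epistatic effect size is
#' \eqn{\delta = \log\Delta_{g_0} - \log\Delta_{g_1} - \log\Delta_{g_2} +
#' \log\Delta_{g_3}}.
#'
#' Gene order is meaningful: for a triple `(A, B, C)`, type `a` tests the
#' interaction between `A` and `B` given that `C` is *not* mutated, and type
#' `b` the same interaction given that `C` *is* mutated.
#'
#' @return `epistasis_types()` returns a tibble with one row per type
#'   (columns `type`, `family`, `g0`..`g3`); `epistasis_type()` returns a
#'   single `epistasis_type` object.
#' @examples
#' epistasis_types()
#' epistasis_type("a")
#' @export
epistasis_types <- function() {
  tibble::tibble(
    type = names(.catalog),
    family = purrr::map_chr(.catalog, "family"),
    g0 = purrr::map_chr(.catalog, ~ .x$quadruple[1]),
    g1 = purrr::map_chr(.catalog, ~ .x$quadruple[2]),
    g2 = purrr::map_chr(.catalog, ~ .x$quadruple[3]),
    g3 = purrr::map_chr(.catalog, ~ .x$quadruple[4])
  )
}

#' @rdname epistasis_types
#' @param type Type label, one of `"pairwise"`, `"a"`..`"l"`.
#' @export
epistasis_type <- function(type) {
  if (inherits(type, "epistasis_type")) return(type)
  if (!is.character(type) || length(type) != 1L || !type %in% names(.catalog)) {
    abort(sprintf(
      "Unknown epistasis type %s. Supported types: %s.",
      deparse(substitute(type)), paste(names(.catalog), collapse = ", ")
    ))
  }
  entry <- .catalog[[type]]
  structure(
    list(
      name = type,
      family = entry$family,
      quadruple = entry$quadruple,
      arity = nchar(entry$quadruple[1])
    ),
    class = "epistasis_type"
  )
}

#' @export
print.epistasis_type <- function(x, ...) {
  cat(sprintf(
    "<epistasis_type %s> (%s): null D_%s * D_%s = D_%s * D_%s\n",
    x$name, x$family, x$quadruple[1], x$quadruple[4], x$quadruple[2], x$quadruple[3]
  ))
  invisible(x)
}

#' Assign genotypes to the four test groups of an epistasis type
#'
#' Maps each genotype (a string of 0/1 bits, one bit per gene, 1 = deleted)
#' to its group index 0-3 within the type's quadruple, or `NA` for genotypes
#' outside the quadruple. Patients with `NA` group take no part in the test
#' but are counted when reporting exclusions.
#'
#' @param genotype Character vector of genotype strings (e.g. `"010"`), or a
#'   0/1 matrix with one column per gene.
#' @param type An epistasis type label or `epistasis_type` object.
#' @return Integer vector of group indices in `0:3`, `NA` = excluded.
#' @examples
#' assign_groups(c("110", "001", "000"), "a") # 3, NA, 0
#' @export
assign_groups <- function(genotype, type) {
  type <- epistasis_type(type)
  if (is.matrix(genotype) || is.data.frame(genotype)) {
    genotype <- apply(as.matrix(genotype), 1L, paste0, collapse = "")
  }
  if (!is.character(genotype)) abort("`genotype` must be genotype strings or a 0/1 matrix.")
  bad <- nchar(genotype) != type$arity
  if (any(bad)) {
    abort(sprintf(
      "Genotype arity mismatch: type `%s` expects %d genes, got genotypes of length %s.",
      type$name, type$arity, paste(unique(nchar(genotype[bad])), collapse = "/")
    ))
  }
  match(genotype, type$quadruple) - 1L
}
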