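#' Construct a repeat annotation lineage
#'
#' A lineage places a repeat cluster in the hierarchical repeat
#' classification used for plant mobile elements: a top-level class
#' (class I retrotransposons, class II DNA transposons, tandem repeats,
#' ribosomal DNA, unclassified repeats, or organellar/chloroplast
#' contamination), then order, superfamily and family labels. Lower levels
#' may be empty, but a set level requires all levels above it to be set
#' (no gaps in the lineage).
#'
#' @param te_class One of `"I"`, `"II"`, `"tandem"`, `"rDNA"`,
#'   `"unclassified"`, `"chloroplast"`.
#' @param order,superfamily,family Optional labels, `""` when unknown.
#' @return A one-row `data.frame` with columns `te_class`, `order`,
#'   `superfamily`, `family`.
#' @examples
#' annotation_lineage("I", "LTR", "Gypsy", "Chromovirus")
#' @export
annotation_lineage <- function(te_class = "unclassified", order = "",
                               superfamily = "", family = "") {
  te_class <- as.character(te_class)
  valid <- c("I", "II", "tandem", "rDNA", "unclassified", "chloroplast")
  if (!te_class %in% valid) {
    stop("unknown te_class '", te_class, "'; must be one of ",
         paste(valid, collapse = ", "))
  }
  lev <- c(order = as.character(order), superfamily = as.character(superfamily),
           family = as.character(family))
  if ((nzchar(lev["family"]) && !nzchar(lev["superfamily"])) ||
      (nzchar(lev["superfamily"]) && !nzchar(lev["order"]))) {
    stop("annotation lineage has gaps: family requires superfamily, ",
         "superfamily requires order")
  }
  data.frame(te_class = te_class, order = lev[["order"]],
             superfamily = lev[["superfamily"]], family = lev[["family"]],
             stringsAsFactors = FALSE)
}

#' @keywords internal
lineage_cols <- c("te_class", "order", "superfamily", "family")

#' Key string identifying a full annotation lineage
#'
#' @param df data.frame with lineage columns.
#' @return Character vector `class/order/superfamily/family`.
#' @keywords internal
lineage_key <- function(df) {
  paste(df$te_class, df$order, df$superfamily, df$family, sep = "/")
}
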