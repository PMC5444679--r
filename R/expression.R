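## RNA-seq expression levels of the phosphofructokinase and
## fructose-1,6-bisphosphatase genes in glucose and xylose media, and the
## fold-change arithmetic applied to them.

#' FPKM levels of the PFK/FBP genes on glucose and xylose
#'
#' Relative mRNA expression (FPKM) of the two phosphofructokinase subunit
#' genes and the fructose-1,6-bisphosphatase gene of *K. marxianus* grown
#' aerobically in glucose or xylose medium.  The glycolytic PFK genes are
#' repressed on xylose while FBP1 is strongly derepressed, bringing the two
#' opposed activities to very similar transcript levels — the expression
#' signature of a poised FBP/PFK substrate cycle.
#'
#' @return data.frame with columns `gene`, `fpkmGlucose`, `fpkmXylose`.
#' @examples
#' expressionFoldChange(kmExpression())
#' @export
kmExpression <- function() {
    data.frame(gene = c("PFK1", "PFK2", "FBP1"),
               fpkmGlucose = c(1640.1, 1856.4, 13.7),
               fpkmXylose = c(341.0, 395.4, 374.6),
               stringsAsFactors = FALSE)
}

#' Expression fold change from glucose to xylose
#'
#' @param records data.frame with columns `gene`, `fpkmGlucose`,
#'   `fpkmXylose` (FPKM values, >= 0).
#' @return the input with a `foldChange` column (xylose / glucose) and a
#'   logical `undefined` column flagging zero-denominator records (whose
#'   fold change is NA, never infinity).
#' @export
expressionFoldChange <- function(records) {
    stopifnot(all(c("gene", "fpkmGlucose", "fpkmXylose") %in%
                  names(records)))
    if (any(records$fpkmGlucose < 0 | records$fpkmXylose < 0))
        stop("FPKM values must be non-negative")
    undefined <- records$fpkmGlucose == 0
    fc <- ifelse(undefined, NA_real_,
                 records$fpkmXylose / records$fpkmGlucose)
    records$foldChange <- fc
    records$undefined <- undefined
    records
}
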