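# Re-exported accessors so the containers are usable without attaching
# their defining packages.

#' @importFrom SummarizedExperiment rowRanges
#' @export
SummarizedExperiment::rowRanges

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay
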