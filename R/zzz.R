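#' @useDynLib icclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom igraph graph_from_edgelist components add_vertices V
#' @importFrom jsonlite write_json
#' @importFrom stats median optimize optim runif rnorm rpois rbinom rbeta qpois qbeta
#' @importFrom utils read.table write.table write.csv head
NULL
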