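# Complexity audit: trainable parameter and multiply-accumulate counting.
# Parameters are counted from the actual arrays (convolution and linear
# weights and biases, batch-norm affine pairs, the two AMTL log-variances).
# MACs follow the profiler convention behind the published per-model
# figures: k^2 * C_in * C_out * H_out * W_out per convolution (divided by
# groups for depthwise), fan_in * fan_out per fully connected layer;
# pooling, activations and batch norm are excluded. The headline figure is
# reported as FLOPs = 2 * MACs (one multiply and one add per accumulate),
# matching how profiler MAC outputs are conventionally printed as GFLOPs.

#' Count trainable parameters
#'
#' @param model an \code{NUnetModel}
#' @return total count, with the per-block breakdown as attribute
#'   \code{"byBlock"}
#' @export
countParams <- function(model) {
  blocks <- model$root$children
  by_block <- vapply(blocks, module_n_params, numeric(1))
  total <- sum(by_block)
  attr(total, "byBlock") <- by_block
  total
}

#' Count multiply-accumulates of one forward pass
#'
#' @param model an \code{NUnetModel}
#' @param inputSize square input resolution (default: the model's
#'   configured size)
#' @return total MAC count, with the per-block breakdown as attribute
#'   \code{"byBlock"} and the doubled FLOPs figure as attribute
#'   \code{"flops"}
#' @export
countMacs <- function(model, inputSize = model$config@inputSize) {
  blocks <- model$root$children
  by_block <- vapply(blocks, module_macs, numeric(1),
                     input_size = inputSize)
  total <- sum(by_block)
  attr(total, "byBlock") <- by_block
  attr(total, "flops") <- 2 * total
  total
}

#' Full complexity report
#'
#' @param model an \code{NUnetModel}
#' @param inputSize square input resolution for the MAC count
#' @return a \linkS4class{ComplexityReport}
#' @export
complexityReport <- function(model, inputSize = model$config@inputSize) {
  p <- countParams(model)
  m <- countMacs(model, inputSize)
  methods::new("ComplexityReport",
               totalParams = as.numeric(p),
               paramsByBlock = attr(p, "byBlock"),
               totalMacs = as.numeric(m),
               macsByBlock = attr(m, "byBlock"),
               totalFlops = 2 * as.numeric(m),
               inputSize = as.integer(inputSize))
}
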