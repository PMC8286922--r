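#' Load the cell-type parameter table
#'
#' Reads the versioned parameter file shipped with the package (or a
#' user-supplied file in the same format) holding the extended
#' quadratic-model coefficients for every cell type. All model defaults
#' live in this one file; nothing is hard-coded in the integrators.
#'
#' @param path Optional path to an alternative parameter table
#'   (tab-delimited, one row per cell type).
#' @return A data.frame with one row per cell type, of class
#'   `"bg_param_table"`.
#' @export
neuron_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "neuron_params.tsv", package = "bgloop")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("cell_type", "capacitance_pF", "quad_gain", "resting_mV",
              "threshold_mV", "peak_mV", "reset_mV", "recovery_rate",
              "recovery_sens", "after_spike_pA", "bias_pA", "slow2_rate",
              "slow2_sens", "slow2_jump_pA", "da_d_scale", "da_hyper_pA")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("parameter table is missing columns: ", paste(miss, collapse = ", "))
  class(tab) <- c("bg_param_table", "data.frame")
  tab
}

#' Parameters for one cell type
#'
#' Extracts and validates the parameter set of a single cell type. The
#' two-variable model is `C dv/dt = k (v - vr)(v - vt) - u + I`,
#' `du/dt = a (b (v - vr) - u)`, with the auxiliary reset `v >= vpeak =>
#' v <- c, u <- u + d`. Thalamocortical relay cells carry an additional
#' second slow variable `w` with its own (slower) rate and sensitivity,
#' entering the voltage equation like `u`. Dopamine couples only to the
#' medium spiny neurons: for D1 cells the after-spike increment shrinks
#' with the dopamine level phi (excitation, rheobase left untouched); for
#' D2 cells a hyperpolarising current proportional to phi is injected
#' (inhibition).
#'
#' @param cell_type One of `"D1_MSN"`, `"D2_MSN"`, `"GPe"`, `"GPi"`,
#'   `"STN"`, `"CTX_RS"`, `"CTX_FS"`, `"TC"`.
#' @param table Parameter table from [neuron_param_table()].
#' @return A named list of class `"neuron_params"`.
#' @export
neuron_params <- function(cell_type, table = neuron_param_table()) {
  cell_type <- match.arg(cell_type, CELL_TYPES)
  row <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("cell type ", cell_type, " not found (or duplicated) in table")
  p <- as.list(row[1, -1])
  p$cell_type <- cell_type
  validate_neuron_params(p)
  class(p) <- "neuron_params"
  p
}

validate_neuron_params <- function(p) {
  num <- p[setdiff(names(p), "cell_type")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && is.finite(x),
                            logical(1))]
  if (length(bad))
    stop("non-finite neuron parameter(s): ", paste(bad, collapse = ", "))
  if (!(p$reset_mV < p$threshold_mV && p$threshold_mV < p$peak_mV))
    stop("require reset_mV < threshold_mV < peak_mV for ", p$cell_type)
  has_w <- p$slow2_rate > 0
  if (has_w && p$cell_type != "TC")
    stop("second slow variable is reserved for TC relay cells")
  if (p$cell_type == "TC" && !has_w)
    stop("TC cells require the second slow variable (slow2_rate > 0)")
  da <- c(p$da_d_scale, p$da_hyper_pA)
  if (any(da != 0) && !(p$cell_type %in% c("D1_MSN", "D2_MSN")))
    stop("dopamine coupling is restricted to the MSN types")
  if (p$cell_type == "D1_MSN" && p$da_d_scale <= 0)
    stop("D1 cells need a positive (excitatory) dopamine coupling")
  if (p$cell_type == "D2_MSN" && p$da_hyper_pA <= 0)
    stop("D2 cells need a positive hyperpolarising dopamine coupling")
  invisible(p)
}

# 15-column numeric vector in the layout the C++ integrators expect
param_vector <- function(p) {
  c(p$capacitance_pF, p$quad_gain, p$resting_mV, p$threshold_mV, p$peak_mV,
    p$recovery_rate, p$recovery_sens, p$reset_mV, p$after_spike_pA,
    p$bias_pA, p$slow2_rate, p$slow2_sens, p$slow2_jump_pA,
    p$da_d_scale, p$da_hyper_pA)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> ", x$cell_type, "\n", sep = "")
  flds <- setdiff(names(x), "cell_type")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}
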