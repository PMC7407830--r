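#' Endpoint registry for the co-culture assay
#'
#' The co-culture model measures seven endpoints: cytokines released by
#' LPS-activated THP-1 macrophages into the basolateral compartment (IL-6,
#' TNF, PGE2), chemokines/eicosanoids released by the intestinal epithelial
#' cell (IEC) monolayer into the apical compartment (IL-8, MCP-1, PGE2), and
#' the transepithelial electrical resistance (TEER) of the monolayer as a
#' barrier-integrity readout. Mediator endpoints are inhibition assays
#' (treatment lowers release towards the inactivated/unstimulated baseline);
#' TEER is an enhancement assay (treatment restores the barrier towards the
#' unstimulated level).
#'
#' @return A data frame with one row per endpoint and columns
#'   `endpoint` (identifier used in data files), `label` (reporting label,
#'   e.g. `"M-IL-6"`), `compartment`, `direction` (`"inhibition"` or
#'   `"enhancement"`), and `reference` — the control class anchoring the
#'   uninflamed level (`"ua"` inactivated for macrophage endpoints, `"us"`
#'   unstimulated for epithelial endpoints and TEER).
#' @examples
#' endpoint_registry()
#' @export
endpoint_registry <- function() {
  data.frame(
    endpoint = c("IL6", "TNF", "PGE2_M", "IL8", "MCP1", "PGE2_IEC", "TEER"),
    label = c("M-IL-6", "M-TNF", "M-PGE2", "IEC-IL-8", "IEC-MCP-1",
              "IEC-PGE2", "TEER"),
    compartment = c(rep("macrophage_basolateral", 3),
                    rep("epithelial_apical", 3),
                    "epithelial_barrier"),
    direction = c(rep("inhibition", 6), "enhancement"),
    reference = c(rep("ua", 3), rep("us", 3), "us"),
    stringsAsFactors = FALSE
  )
}

endpoint_info <- function(endpoint) {
  reg <- endpoint_registry()
  i <- match(endpoint, reg$endpoint)
  if (is.na(i)) {
    i <- match(endpoint, reg$label)
  }
  if (is.na(i)) {
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

#' @keywords internal
control_classes <- function() c("s", "ua", "us", "bud", "treated")

# columns every long-format assay table must carry
assay_columns <- function() {
  c("endpoint", "compartment", "treatment", "control_class",
    "concentration_ug_ml", "time_h", "replicate", "value",
    "value_before", "value_after")
}
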