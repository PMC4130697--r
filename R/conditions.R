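#' @keywords internal
#' @importFrom stats simulate rnorm sd
#' @importFrom utils write.table packageVersion
#' @importFrom tools md5sum
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_avrot <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "avrot_error", "error"),
                      call = call))
}

.stop_degenerate <- function(msg) .stop_avrot(msg, "avrot_degenerate_geometry")
.stop_missing    <- function(msg) .stop_avrot(msg, "avrot_missing_landmark")
.stop_domain     <- function(msg) .stop_avrot(msg, "avrot_domain_error")
.stop_parse      <- function(msg) .stop_avrot(msg, "avrot_parse_error")
.stop_validation <- function(msg) .stop_avrot(msg, "avrot_validation_error")
.stop_io         <- function(msg) .stop_avrot(msg, "avrot_io_error")

.warn_over_limit <- function(alpha_deg, limit = 30) {
  warning(warningCondition(
    sprintf("measured rotation %.2f deg exceeds the %g deg validity limit of the method",
            alpha_deg, limit),
    class = c("avrot_over_limit", "avrot_warning", "warning")))
}
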