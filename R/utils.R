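# internal helpers

M_PER_INCH <- 0.0254

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# thousandths of an inch -> metres
mil_to_m <- function(mils) mils / 1000 * M_PER_INCH

mm_to_m <- function(x) x / 1000
m_to_mm <- function(x) x * 1000
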