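# Shared fixtures, built once per test run.

std_ref <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_reference(31133, 0.4, seed = 42)
    val
  }
})

std_design <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- design_tiling(std_ref(), gregion("chrS", 0, 31133), flank = 0)
    }
    val
  }
})

# wide-tile design whose pair spans sit near the read-length median
wide_design_env <- new.env()
wide_design <- function() {
  if (is.null(wide_design_env$ref)) {
    wide_design_env$ref <- make_reference(40000, 0.4, seed = 42)
    wide_design_env$design <- design_tiling(
      wide_design_env$ref, gregion("chrS", 0, 40000), flank = 0
    )
  }
  wide_design_env
}

std_region <- function() gregion("chrS", 0, 31133)

std_transcript <- function() make_transcript(std_region())
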