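# The end-to-end acceptance expectations include checks that are
# documented as unattainable at the study's blur/noise regime (see the
# package vignette); their failures must not truncate the rest of the
# suite, so lift the progress reporter's failure cap.
options(testthat.progress.max_fails = 10000L)
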