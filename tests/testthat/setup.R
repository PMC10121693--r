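# report every block even when several quantitative checks fail: without
# this the progress reporter stops the whole run after ten failures
options(testthat.progress.max_fails = 200)
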