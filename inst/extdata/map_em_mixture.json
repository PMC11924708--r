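{"components":[{"alpha":10.59,"beta":54.71},{"alpha":4.53,"beta":17.92}],"weights":[0.58,0.42]}
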