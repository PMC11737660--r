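# Synthetic stand-in for a high-risk token lexicon (suicide-related terms,
# cutting instruments, psychopathology signs). The published lexicon is
# Korean and not deposited; these English tokens illustrate the format:
# one token per line, '#' comments allowed.
suicide
suicidal
overdose
knife
cutter
blade
razor
cutting
depression
depressed
trauma
hopeless
worthless
insomnia
panic
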