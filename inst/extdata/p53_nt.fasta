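>p53_NT sp|P04637|1-94 offset=1 human p53 N-terminal IDR (transactivation + proline-rich region)
MEEPQSDPSVEPPLSQETFSDLWKLLPENNVLSPLPSQAMDDLMLSPDDIEQWFTEDPGP
DEAPRMPEAAPPVAPAPAAPTPAAPAPAPSWPLS
>p53_NT_fragment sp|P04637|37-65 offset=37 FAM-labelled titration fragment
SQAMDDLMLSPDDIEQWFTEDPGPDEAPR
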