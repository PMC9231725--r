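motif,panel,svm,preps,freq,fpb,observed_prenylation,svm_cleave,freq_cleave,observed_cleavage
CIIS,proteome,+,+,+,+,+,+,+,+
CIKS,proteome,-,-,-,-,-,NA,NA,NA
CIIL,proteome,+,+,+,-,+,+,+,+
CIDL,proteome,-,-,-,-,-,NA,NA,NA
CVIM,proteome,+,+,+,-,+,+,+,+
CVKM,proteome,-,-,-,-,+,+,-,-
CSII,proteome,+,+,+,+,+,+,+,+
CSEI,proteome,-,-,-,-,-,NA,NA,NA
CSNA,proteome,-,-,+,-,+,-,-,-
CYNA,proteome,-,-,-,+,+,-,-,-
CSGL,proteome,-,-,+,-,-,NA,NA,NA
CSGK,proteome,-,-,-,-,-,NA,NA,NA
CKQS,proteome,+,+,+,-,+,-,-,-
CFIF,proteome,+,+,-,-,+,+,-,-
CAPY,proteome,+,+,-,-,+,-,-,-
CTVA,proteome,+,+,+,+,+,+,+,+
CALD,proteome,+,-,+,+,+,-,+,-
CAVS,proteome,+,+,+,+,+,-,+,+
CIQF,proteome,+,+,+,-,+,+,-,-
CAAQ,reporter,+,-,+,-,+,NA,NA,NA
CAHQ,reporter,+,-,+,-,+,NA,NA,NA
CASA,reporter,+,-,+,-,+,NA,NA,NA
CKQH,reporter,+,-,+,-,+,NA,NA,NA
CNLI,reporter,+,-,+,-,+,NA,NA,NA
CSFL,reporter,+,-,+,-,+,NA,NA,NA
CVAA,reporter,+,-,+,-,+,NA,NA,NA
CVFM,reporter,+,-,+,-,+,NA,NA,NA
CKQG,reporter,-,+,+,-,+,NA,NA,NA
CKQL,reporter,-,+,+,-,+,NA,NA,NA
CQTS,reporter,-,+,-,-,+,NA,NA,NA
CQSQ,reporter,+,+,-,-,+,NA,NA,NA
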