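january
february
march
april
may
june
july
august
september
october
november
december
austria
australia
belgium
brazil
canada
china
denmark
finland
france
germany
india
italy
japan
netherlands
norway
poland
portugal
russia
spain
sweden
switzerland
united kingdom
united states
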