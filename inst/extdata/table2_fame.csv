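species,PW,BG-11
C11:0,ND,ND
C12:0,ND,ND
C14:0,ND,ND
C15:0,ND,ND
C16:0,19.2,21.0
C17:0,ND,ND
C18:0,10.2,11.2
C20:0,ND,ND
C21:0,ND,0.5
C22:0,0.3,ND
C24:0,ND,ND
C28:0,1.2,1.0
C15:1,ND,ND
16:1n7c,6.6,7.5
C17:1,ND,ND
C18:1n9t,36.0,33.6
C20:1,ND,ND
C16:2n4,8.0,5.8
C16:3,ND,ND
C16:4,ND,ND
C18:2,10.2,12.4
C18:2ω6,5.3,5.1
C18:3 alpha,ND,ND
C18:4,ND,ND
C20:3c,ND,ND
C20:3t,ND,ND
C20:4,ND,ND
C22:6,ND,ND
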