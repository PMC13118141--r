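# Public-suffix rule snapshot (plain rules only, one per line).
# Registered (base) domain = matched suffix plus one preceding label.
# Unknown top-level labels fall back to the default single-label rule.
com
org
net
edu
gov
mil
int
io
co
ai
app
dev
tv
me
fm
gg
ly
sh
xyz
info
biz
name
pro
cloud
online
site
store
tech
example
uk
co.uk
org.uk
ac.uk
gov.uk
me.uk
net.uk
au
com.au
net.au
org.au
edu.au
gov.au
jp
co.jp
ne.jp
or.jp
ac.jp
go.jp
kr
co.kr
or.kr
cn
com.cn
net.cn
org.cn
edu.cn
gov.cn
in
co.in
net.in
org.in
br
com.br
net.br
org.br
mx
com.mx
nz
co.nz
net.nz
org.nz
za
co.za
de
fr
it
es
nl
se
no
fi
dk
ch
at
be
pl
ru
com.ru
ca
us
eu
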